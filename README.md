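# pentachroma

Analysis of color-vision physiology in cichlid fishes — from
electroretinogram (ERG) response–intensity curves to cone-pigment
identification, opponency modelling, opsin expression and cohort-level
statistics.

Lake Malawi cichlids carry seven cone opsin genes but express them
differentially, so individual fish build their color vision from different
*subsets* of four or five spectrally distinct cone pigments — up to true
pentachromacy. Establishing which cones are functional in a given fish
requires a chain of analyses that this package implements as tested,
reusable components for visual ecologists and sensory physiologists:

- **Naka-Rushton fitting** of b-wave response–intensity (RI) curves,
  `R(I) = Rmax·I/(I + K)`, giving spectral sensitivity `S(λ) = 1/K(λ)` on a
  320–700 nm / 20 nm grid, normalized as log relative sensitivity
  (`fit_naka_rushton()`, `sensitivity_from_ri()`). Edge wavelengths whose RI
  curve fails to saturate are refitted with `Rmax` pinned to the interior
  neighbor.
- **Visual-pigment absorbance templates** for A1 (retinal) and A2
  (3,4-didehydroretinal) chromophores, their mixtures
  `A(a) = (1−a)·A1 + a·A2`, the A1→A2 red shift of the absorbance peak
  (`a2_lambda_max()`: 523 → 560 nm for RH2a, 560 → 626 nm for LWS), and
  ocular-media correction (`mixed_template()`, `apply_lens_transmission()`).
- **Cone-mechanism identification** across chromatic-adaptation backgrounds:
  sensitivity peaks must appear under at least two isolation conditions and,
  in the UV range, track the adaptation direction (UV cone vs β-band); the
  retinal A2 proportion is estimated from the long-wavelength limb; pigment
  classes are assigned by least-squares template fits and matched against
  the catalogue of published cone subsets (`identify_individual()`).
- **Multiple-cone mechanism (MCM) opponency model**: piecewise
  reconstruction of sensitivity between notches as signed template sums
  `S(λ) = Σ k_i·A_i(λ)`, selecting the interaction with the fewest cones,
  the best fit under all backgrounds, and sign-consistent (opponent /
  nonopponent) contributions (`find_notches()`, `select_interaction()`).
- **Quantum catch** `Q = ∫ A(λ)·E(λ) dλ` over 300–800 nm for background
  design and reflectance-based conspicuousness (`quantum_catch()`,
  `reflectance_catch()`).
- **Relative opsin expression** from qPCR quantification cycles,
  `T_g/T_all = (1+E_g)^(−Cq_g) / Σ_h (1+E_h)^(−Cq_h)`, with per-gene
  sex-difference t-tests at the Bonferroni-corrected α = 0.05/6
  (`relative_expression()`, `sex_difference_tests()`).
- **Cohort statistics**: subset and pigment frequencies by species and sex,
  cone-class count distributions, and an exact two-tailed Fisher test for
  2×k tables by complete enumeration (`tally_subsets()`,
  `fisher_species()`).
- **A synthetic-cohort generator** with full ground truth — cone subsets
  drawn with the published frequencies, divisive Weber-style chromatic
  adaptation, opponency-shaped curves, RI records and qPCR records — so
  every stage of the pipeline can be validated end-to-end
  (`simulate_cohort()`, `recover_cohort()`).

The package ships a plain-text transcription of the published
per-individual results (34 fish of *Metriaclima zebra*, *Melanochromis
auratus* and *Protomelas taeniolatus*) as its reference cohort.

## Worked example

```r
library(pentachroma)

cohort <- load_cohort()                  # packaged study cohort
head(tally_subsets(cohort, "species"))
#>         group subset n frequency
#> 3  M. auratus      3 4      36.4
#> 4  M. auratus      4 1       9.1
#> 5  M. auratus      5 1       9.1
#> 6  M. auratus      6 1       9.1
#> 8  M. auratus      7 1       9.1
#> 10 M. auratus      8 2      18.2

class_count_distribution(cohort)         # % of fish with 3/4/5 cone classes
#>  3  4  5
#>  3 56 41

fisher_species(cohort, "SWS1")$p_value   # exact 2x3 test by enumeration
#> [1] 0.000542

# synthetic cohort with known ground truth, recovered by the full pipeline
cfg <- synthetic_config(log_sens_sigma = 0, response_sigma = 0, cq_sigma = 0)
coh <- simulate_cohort(cfg, seed = 1)
rec <- recover_cohort(coh)
mean(rec$set_match)
#> [1] 0.9705882
```

The tallies say that 41% of fish used five cone classes and 56% four; the
subset-3 row reproduces the 36.4% frequency of the most common
*M. auratus* subset; the Fisher p-value (0.0005) shows that the frequency
of the UV-sensitive SWS1 pigment differs strongly across the three species.
The synthetic round trip recovers the generating pigment set for 33 of 34
noise-free individuals drawn with the study's subset frequencies (the one
miss is an individual whose high-A2 RH2a limb is spectrally degenerate with
a low-A2 LWS; on the calibration design with A2 pinned at 0/25/50% recovery
is complete).

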