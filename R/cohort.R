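#' Load the packaged study cohort table
#'
#' One row per individual: species, sex, subset label, estimated A2
#' proportion, pigment presence flags, fitted lambda-max and template
#' R-squared per pigment, and the cone-class count. This is a transcription
#' of the published per-individual results (34 fish of three Lake Malawi
#' cichlid species). A truncated RH2b entry for individual TF1 is stored as
#' missing lambda-max; its presence flag follows its subset's catalogue row.
#'
#' @param path Optional path to a user cohort table in the same layout;
#'   default loads the packaged fixture.
#' @return Data frame.
#' @export
load_cohort <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table2_individuals.tsv",
                        package = "pentachroma", mustWork = TRUE)
  d <- utils::read.delim(path, check.names = FALSE)
  flags <- names(pigment_classes())
  if (!all(c("individual", "species", "sex", "subset", "n_cones", flags)
           %in% names(d)))
    stop("cohort table missing required columns", call. = FALSE)
  stopifnot(all(rowSums(d[, flags]) == d$n_cones))
  d
}

group_sizes <- function(cohort, by) {
  key <- switch(by,
                species = cohort$species,
                species_sex = paste(cohort$species, cohort$sex),
                stop("by must be 'species' or 'species_sex'", call. = FALSE))
  table(key)
}

#' Frequency of cone pigment subsets per group
#'
#' @param cohort Cohort data frame ([load_cohort()] layout).
#' @param by Grouping: `"species"` or `"species_sex"`.
#' @param digits Decimal places for the percentage (default 1, the reporting
#'   convention of the published tables); `NULL` for exact values.
#' @return Data frame: `group`, `subset`, `n`, `frequency` (percent).
#' @export
tally_subsets <- function(cohort, by = "species", digits = 1) {
  sizes <- group_sizes(cohort, by)
  key <- if (by == "species") cohort$species else
    paste(cohort$species, cohort$sex)
  tab <- table(key, cohort$subset)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "subset", "n")
  out <- out[out$n > 0, , drop = FALSE]
  if (any(sizes == 0)) stop("empty group: ",
                            names(sizes)[sizes == 0][1], call. = FALSE)
  out$frequency <- 100 * out$n / as.numeric(sizes[out$group])
  if (!is.null(digits)) out$frequency <- round(out$frequency, digits)
  rownames(out) <- NULL
  out[order(out$group, as.numeric(out$subset)), ]
}

#' Frequency of each cone pigment per group
#'
#' Percentage of individuals in each group whose retina carries each pigment
#' class.
#'
#' @inheritParams tally_subsets
#' @param digits Decimal places; default `NULL` (exact). The published
#'   prose rounds to integer percent.
#' @return Data frame: `group`, `pigment`, `n_present`, `frequency`.
#' @export
pigment_frequency <- function(cohort, by = "species", digits = NULL) {
  sizes <- group_sizes(cohort, by)
  key <- if (by == "species") cohort$species else
    paste(cohort$species, cohort$sex)
  flags <- names(pigment_classes())
  out <- do.call(rbind, lapply(names(sizes), function(gr) {
    d <- cohort[key == gr, flags, drop = FALSE]
    data.frame(group = gr, pigment = flags,
               n_present = unname(colSums(d)),
               frequency = 100 * unname(colSums(d)) / nrow(d))
  }))
  if (!is.null(digits)) out$frequency <- round(out$frequency, digits)
  rownames(out) <- NULL
  out
}

#' Distribution of cone-class counts across the cohort
#'
#' @param cohort Cohort data frame.
#' @param digits Decimal places (default 0, the prose convention).
#' @return Named numeric vector: percent of individuals per cone-class
#'   count.
#' @export
class_count_distribution <- function(cohort, digits = 0) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  tab <- table(cohort$n_cones)
  p <- 100 * as.numeric(tab) / nrow(cohort)
  if (!is.null(digits)) p <- round(p, digits)
  stats::setNames(p, names(tab))
}

#' Exact Fisher test for a 2 x k contingency table by complete enumeration
#'
#' Enumerates every table with the observed margins, computes each table's
#' multivariate hypergeometric probability, and sums the probabilities of
#' all tables no more probable than the observed one (the common two-tailed
#' definition).
#'
#' @param tab Integer matrix with 2 rows (e.g. pigment present/absent) and k
#'   columns (groups).
#' @return List: `p_value`, `n_tables` enumerated.
#' @export
fisher_exact_2xk <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L) stop("table must have 2 rows", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers", call. = FALSE)
  col_n <- colSums(tab)
  A <- sum(tab[1, ])
  N <- sum(tab)
  if (A == 0 || A == N) {
    warning("degenerate margins; p = 1")
    return(list(p_value = 1, n_tables = 1L))
  }
  k <- ncol(tab)
  # log probability of a candidate first row `a` given fixed margins
  logp <- function(a) sum(lchoose(col_n, a)) - lchoose(N, A)
  obs <- logp(tab[1, ])
  total <- 0
  count <- 0L
  rec <- function(j, a_head, remaining) {
    if (j == k) {
      if (remaining > col_n[k]) return()
      a <- c(a_head, remaining)
      lp <- logp(a)
      count <<- count + 1L
      if (lp <= obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    lo <- max(0L, remaining - sum(col_n[(j + 1L):k]))
    hi <- min(col_n[j], remaining)
    if (lo > hi) return()
    for (aj in lo:hi) rec(j + 1L, c(a_head, aj), remaining - aj)
  }
  rec(1L, integer(0), A)
  list(p_value = min(1, total), n_tables = count)
}

#' Fisher's exact test of pigment frequency across species
#'
#' Builds the 2 x 3 presence/absence by species table for one pigment class
#' and runs [fisher_exact_2xk()]. Significance is judged at the
#' Bonferroni-corrected alpha = 0.05/6 = 0.0083 for the six pigment classes.
#'
#' @param cohort Cohort data frame.
#' @param pigment Pigment class name.
#' @param alpha Significance threshold (default 0.05/6).
#' @return List: `pigment`, `table`, `p_value`, `significant`.
#' @export
fisher_species <- function(cohort, pigment, alpha = 0.05 / 6) {
  if (!pigment %in% names(pigment_classes()))
    stop("unknown pigment: ", pigment, call. = FALSE)
  present <- tapply(cohort[[pigment]], cohort$species, sum)
  n <- table(cohort$species)
  tab <- rbind(present = as.numeric(present),
               absent = as.numeric(n) - as.numeric(present))
  colnames(tab) <- names(n)
  res <- fisher_exact_2xk(tab)
  list(pigment = pigment, table = tab, p_value = res$p_value,
       significant = res$p_value < alpha)
}

#' Load the packaged subset-frequency table
#'
#' Per-subset frequencies by species and sex, as published; also the default
#' subset priors of the synthetic cohort generator.
#'
#' @return Data frame: `subset`, `n_cones`, `species`, `sex`, `frequency`.
#' @export
subset_frequencies <- function() {
  path <- system.file("extdata", "table3_frequencies.tsv",
                      package = "pentachroma", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}
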