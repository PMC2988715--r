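#' Read qPCR records from delimited text
#'
#' Columns: `individual`, `species`, `sex`, `gene`, `replicate`, `Cq`,
#' `efficiency`. Technical replicates (typically triplicates) are averaged on
#' load. No-template (`NTC`) and no-reverse-transcriptase (`NoRT`/`No-RT`)
#' control rows are accepted and excluded, with the excluded count reported
#' as a message.
#'
#' @param path File path (tab or comma delimited).
#' @return Data frame with one row per individual and gene: `individual`,
#'   `species`, `sex`, `gene`, `Cq` (replicate mean), `efficiency`
#'   (replicate mean), `n_replicates`.
#' @export
read_qpcr <- function(path) {
  d <- read_delim_auto(path)
  need <- c("individual", "species", "sex", "gene", "replicate", "Cq",
            "efficiency")
  if (!all(need %in% names(d)))
    stop("qPCR file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ctrl <- toupper(gsub("[^A-Za-z]", "", d$individual)) %in%
    c("NTC", "NORT") |
    toupper(gsub("[^A-Za-z]", "", d$gene)) %in% c("NTC", "NORT")
  if (any(ctrl)) {
    message(sum(ctrl), " control rows (NTC/No-RT) excluded")
    d <- d[!ctrl, , drop = FALSE]
  }
  agg <- stats::aggregate(cbind(Cq, efficiency) ~ individual + species +
                            sex + gene, data = d, FUN = mean)
  n <- stats::aggregate(replicate ~ individual + species + sex + gene,
                        data = d, FUN = length)
  agg$n_replicates <- n$replicate[match(
    paste(agg$individual, agg$gene), paste(n$individual, n$gene))]
  agg
}

#' Relative opsin expression for one individual
#'
#' Expression of gene g relative to all cone opsins of individual i:
#' `T_g / T_all = (1 + E_g)^(-Cq_g) / sum_h (1 + E_h)^(-Cq_h)`,
#' where `E` is the amplification efficiency as a fraction (so the base
#' `1 + E` lies in \[1, 2\]) and `Cq` the replicate-averaged fractional
#' quantification cycle.
#'
#' @param records Data frame for a single individual with columns `gene`,
#'   `Cq`, `efficiency` (replicate-averaged).
#' @return Named numeric vector of expression fractions summing to 1.
#' @export
relative_expression <- function(records) {
  if (nrow(records) < 1L) stop("no qPCR records", call. = FALSE)
  if (anyNA(records$efficiency))
    stop("missing amplification efficiency; no default is assumed",
         call. = FALSE)
  if (any(records$efficiency > 1 + 1e-9))
    stop("efficiency must be a fraction in [0, 1] (1 + E in [1, 2]); ",
         "percent-style efficiencies must be divided by 100", call. = FALSE)
  if (any(records$efficiency < 0))
    stop("efficiency must be non-negative", call. = FALSE)
  if (any(records$Cq <= 0)) stop("Cq must be positive", call. = FALSE)
  t_g <- (1 + records$efficiency)^(-records$Cq)
  stats::setNames(t_g / sum(t_g), records$gene)
}

#' Expression profiles for every individual in a qPCR table
#'
#' @param records Data frame as returned by [read_qpcr()].
#' @return Data frame: `individual`, `species`, `sex`, `gene`, `fraction`.
#' @export
expression_profiles <- function(records) {
  out <- lapply(split(records, records$individual), function(d) {
    f <- relative_expression(d)
    data.frame(individual = d$individual[1], species = d$species[1],
               sex = d$sex[1], gene = names(f), fraction = unname(f))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group means and standard errors of expression fractions
#'
#' @param profiles Data frame from [expression_profiles()].
#' @return Data frame: `species`, `sex`, `gene`, `n`, `mean`, `sem` (`NA`
#'   with a warning message attached for singleton groups).
#' @export
group_summary <- function(profiles) {
  sp <- split(profiles, list(profiles$species, profiles$sex, profiles$gene),
              drop = TRUE)
  out <- lapply(sp, function(d) {
    n <- nrow(d)
    data.frame(species = d$species[1], sex = d$sex[1], gene = d$gene[1],
               n = n, mean = mean(d$fraction),
               sem = if (n > 1) stats::sd(d$fraction) / sqrt(n) else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$n == 1L)) warning("groups of size 1: SEM undefined")
  res[order(res$species, res$sex, res$gene), ]
}

#' Cochran's C test of variance homogeneity
#'
#' `C = max(s_j^2) / sum(s_j^2)` over groups; the p-value uses the standard
#' F-based bound with the average group size.
#'
#' @param x Numeric response vector.
#' @param g Grouping factor.
#' @return List: `statistic`, `p_value`, `k`, `n_avg`.
#' @export
cochran_c_test <- function(x, g) {
  g <- factor(g)
  v <- tapply(x, g, stats::var)
  k <- length(v)
  if (k < 2L || anyNA(v)) stop("need >= 2 groups with >= 2 values each",
                               call. = FALSE)
  C <- max(v) / sum(v)
  n <- mean(tapply(x, g, length))
  if (C >= 1 - 1e-12) return(list(statistic = C, p_value = 0, k = k,
                                  n_avg = n))
  Fstat <- (k - 1) * C / (1 - C)
  p <- min(1, k * stats::pf(Fstat, n - 1, (n - 1) * (k - 1),
                            lower.tail = FALSE))
  list(statistic = C, p_value = p, k = k, n_avg = n)
}

#' Per-gene sex-difference tests of relative opsin expression
#'
#' Two-sample t-tests per gene between females and males of one species, at
#' a Bonferroni-corrected error rate alpha = 0.05/6 = 0.0083 for the six
#' opsin genes. Kolmogorov-Smirnov normality checks (per sex, against a
#' normal with the sample moments) and Cochran's C homogeneity of variance
#' are reported alongside. The t-test assumes equal variances by default,
#' consistent with the homogeneity screening; set `var_equal = FALSE` for
#' Welch.
#'
#' @param profiles Data frame from [expression_profiles()].
#' @param species Species to test.
#' @param alpha Significance threshold (default 0.05/6).
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @return Data frame per gene: `t`, `df`, `p_value`, `significant`,
#'   `ks_p_female`, `ks_p_male`, `cochran_C`, `cochran_p`, `degenerate`.
#' @export
sex_difference_tests <- function(profiles, species, alpha = 0.05 / 6,
                                 var_equal = TRUE) {
  d <- profiles[profiles$species == species, , drop = FALSE]
  sexes <- unique(d$sex)
  if (length(sexes) != 2L)
    stop("need exactly two sexes for species ", species, call. = FALSE)
  out <- lapply(split(d, d$gene), function(dg) {
    a <- dg$fraction[dg$sex == sexes[1]]
    b <- dg$fraction[dg$sex == sexes[2]]
    if (length(a) < 2L || length(b) < 2L)
      stop("need n >= 2 per sex for gene ", dg$gene[1], call. = FALSE)
    degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (degenerate) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(a) +
                   length(b) - 2), p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
    }
    ks <- function(x) {
      if (stats::sd(x) == 0) return(NA_real_)
      suppressWarnings(stats::ks.test(x, "pnorm", mean(x),
                                      stats::sd(x))$p.value)
    }
    cc <- if (degenerate) list(statistic = NA_real_, p_value = NA_real_)
          else cochran_c_test(dg$fraction, dg$sex)
    data.frame(gene = dg$gene[1], t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               significant = tt$p.value < alpha,
               ks_p_female = ks(dg$fraction[tolower(dg$sex) %in%
                                              c("f", "female")]),
               ks_p_male = ks(dg$fraction[tolower(dg$sex) %in%
                                            c("m", "male")]),
               cochran_C = cc$statistic, cochran_p = cc$p_value,
               degenerate = degenerate)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
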