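# Tissue-distribution differential analysis and behavioural summary
# statistics (novel-object recognition index, pooled two-sample t-test).

#' Biological-matrix code map
#'
#' The six matrices sampled in the distribution study, coded 1-6.
#'
#' @return Named character vector: code (as name) to matrix name.
#' @export
matrix_codes <- function() {
  c("1" = "plasma", "2" = "urine", "3" = "feces",
    "4" = "liver", "5" = "kidney", "6" = "brain")
}

# Parse "1,2,3" (or "-"/NA/"" = none) into a validated integer set.
parse_matrix_codes <- function(text) {
  if (length(text) != 1L || is.na(text) || text %in% c("", "-")) return(integer())
  v <- as.integer(strsplit(text, ",", fixed = TRUE)[[1]])
  bad <- v[!v %in% 1:6 | is.na(v)]
  if (length(bad) || anyNA(v)) stop("unknown matrix code: ",
                                    paste(bad, collapse = ", "))
  sort(unique(v))
}

#' Per-metabolite distribution records from a feature table
#'
#' A metabolite's per-group distribution is the union of the matrix
#' codes of all its adduct rows (detection in either polarity counts as
#' detection).
#'
#' @param features Feature table with columns `metabolite`, `sham`,
#'   `model` (comma-separated code strings).
#' @return Data.frame with `metabolite` and list columns `sham`,
#'   `model` of integer code sets.
#' @export
distribution_records <- function(features) {
  mets <- unique(features$metabolite)
  sham <- lapply(mets, function(m) {
    rows <- features[features$metabolite == m, , drop = FALSE]
    sort(unique(unlist(lapply(rows$sham, parse_matrix_codes))))
  })
  model <- lapply(mets, function(m) {
    rows <- features[features$metabolite == m, , drop = FALSE]
    sort(unique(unlist(lapply(rows$model, parse_matrix_codes))))
  })
  out <- data.frame(metabolite = mets, stringsAsFactors = FALSE)
  out$sham <- sham
  out$model <- model
  out
}

#' Sham-only / model-only distribution differences per metabolite
#'
#' Set differences of the per-group matrix sets; metabolites with both
#' differences empty are concordant between groups.
#'
#' @param records Output of [distribution_records()].
#' @return Data.frame with `metabolite`, list columns `sham_only` and
#'   `model_only` (integer code sets), their readable name counterparts,
#'   and logical `concordant`.
#' @export
differential_report <- function(records) {
  nm <- matrix_codes()
  sham_only <- lapply(seq_len(nrow(records)), function(i)
    setdiff(records$sham[[i]], records$model[[i]]))
  model_only <- lapply(seq_len(nrow(records)), function(i)
    setdiff(records$model[[i]], records$sham[[i]]))
  out <- data.frame(metabolite = records$metabolite,
                    stringsAsFactors = FALSE)
  out$sham_only <- sham_only
  out$model_only <- model_only
  out$sham_only_names <- vapply(sham_only, function(s)
    paste(nm[as.character(s)], collapse = ","), character(1))
  out$model_only_names <- vapply(model_only, function(s)
    paste(nm[as.character(s)], collapse = ","), character(1))
  out$concordant <- lengths(sham_only) == 0L & lengths(model_only) == 0L
  out
}

#' Blood-brain-barrier penetrance differences
#'
#' Metabolites whose brain detection (matrix code 6) differs between the
#' model and sham groups.
#'
#' @param records Output of [distribution_records()].
#' @return List with `brain_model_only` and `brain_sham_only`
#'   (character vectors of metabolite ids).
#' @export
bbb_penetrance <- function(records) {
  in_brain <- function(col) vapply(records[[col]], function(s) 6L %in% s,
                                   logical(1))
  sham <- in_brain("sham"); model <- in_brain("model")
  list(brain_model_only = records$metabolite[model & !sham],
       brain_sham_only = records$metabolite[sham & !model])
}

#' Novel-object recognition index
#'
#' RI = novel-object exploration time over total exploration time,
#' T_B / (T_A2 + T_B); scale-invariant and in \[0, 1\].
#'
#' @param t_novel,t_familiar Exploration times (seconds, >= 0; their sum
#'   must be positive).
#' @return RI in \[0, 1\].
#' @export
recognition_index <- function(t_novel, t_familiar) {
  stopifnot(all(t_novel >= 0), all(t_familiar >= 0))
  tot <- t_novel + t_familiar
  if (any(tot <= 0)) stop("total exploration time is zero: RI undefined")
  t_novel / tot
}

#' Group summary (mean, SD, n) for summary-statistic tests
#'
#' @param mean,sd,n Group mean, standard deviation (>= 0), sample size
#'   (>= 2).
#' @return A `group_summary` list.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student's t by default (df = n_a + n_b - 2), or
#' Welch's unequal-variance form with `welch = TRUE`
#' (Welch-Satterthwaite df). Two-sided p by default.
#'
#' @param a,b [group_summary()] objects.
#' @param two_sided Two-sided p-value (default TRUE).
#' @param welch Use Welch's form (default FALSE).
#' @return List: `t`, `df`, `p`.
#' @examples
#' pooled_t_test(group_summary(0.6545, 0.1148, 10),
#'               group_summary(0.5131, 0.1046, 12))  # p = 0.007
#' @export
pooled_t_test <- function(a, b, two_sided = TRUE, welch = FALSE) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  d <- a$mean - b$mean
  if (welch) {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  if (se == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1))
    stop("zero variance with unequal means: t undefined")
  }
  t <- d / se
  p <- if (two_sided) 2 * stats::pt(-abs(t), df) else stats::pt(-t, df)
  list(t = t, df = df, p = p)
}

#' Bonferroni adjustment
#'
#' Each p-value multiplied by `m` and capped at 1.
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of comparisons (>= length of the vector).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(m >= length(p_values))
  if (length(p_values) == 0L) return(numeric())
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}
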