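#' Coerce and validate a stage confusion matrix
#'
#' Validates a square, non-negative integer count matrix labeled with
#' the [sleep_stages()] alphabet and reorders rows and columns into the
#' canonical order `Art, W, N1, N2, N3, REM`. Rows are rating A,
#' columns rating B.
#'
#' @param m a labeled square numeric matrix of counts.
#' @return A `confusion_matrix` (integer matrix with canonical dimnames).
#' @export
as_confusion_matrix <- function(m) {
  if (inherits(m, "confusion_matrix")) return(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_earsleep("confusion matrix must be square", "earsleep_validation_error")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_earsleep("confusion matrix needs row and column stage labels",
                  "earsleep_validation_error")
  }
  validate_stage_labels(rownames(m), "row")
  validate_stage_labels(colnames(m), "column")
  if (!setequal(rownames(m), colnames(m))) {
    stop_earsleep("row and column label sets differ", "earsleep_validation_error")
  }
  if (any(!is.finite(m)) || any(m < 0) || any(abs(m - round(m)) > 1e-9)) {
    stop_earsleep("counts must be non-negative integers",
                  "earsleep_validation_error")
  }
  ord <- intersect(sleep_stages(), rownames(m))
  out <- matrix(0L, length(sleep_stages()), length(sleep_stages()),
                dimnames = list(sleep_stages(), sleep_stages()))
  out[ord, ord] <- as.integer(round(m[ord, ord]))
  if (sum(out) == 0) {
    stop_earsleep("confusion matrix has zero total count",
                  "earsleep_validation_error")
  }
  structure(out, class = c("confusion_matrix", "matrix", "array"))
}

#' Align two hypnograms epoch by epoch
#'
#' Pairs the two ratings epochwise, truncating to the shorter hypnogram
#' and optionally to `max_epochs`. Truncation expresses per-participant
#' restrictions such as using only the first 5 h 20 min (640 epochs of
#' 30 s) of a night when part of the recording is unusable.
#'
#' @param h1,h2 [hypnogram()] objects with equal epoch length.
#' @param max_epochs optional cap on the number of paired epochs.
#' @return A data frame with character columns `a` and `b`.
#' @export
align_hypnograms <- function(h1, h2, max_epochs = NULL) {
  stopifnot(inherits(h1, "hypnogram"), inherits(h2, "hypnogram"))
  if (h1$epoch_length != h2$epoch_length) {
    stop_earsleep("hypnograms have different epoch lengths",
                  "earsleep_validation_error")
  }
  n <- min(length(h1$stages), length(h2$stages))
  if (!is.null(max_epochs)) {
    if (!is_scalar_number(max_epochs) || max_epochs < 1) {
      stop_earsleep("max_epochs must be a positive count",
                    "earsleep_validation_error")
    }
    n <- min(n, as.integer(max_epochs))
  }
  if (n < 1L) {
    stop_earsleep("hypnograms have no overlapping epochs",
                  "earsleep_validation_error")
  }
  data.frame(a = h1$stages[seq_len(n)], b = h2$stages[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Cross-tabulate paired stage ratings
#'
#' Counts, for every ordered stage pair, the epochs rated `a` by the
#' first rating and `b` by the second. Concatenating participants before
#' tabulating is equivalent to summing their per-participant matrices.
#'
#' @param pairs data frame with columns `a` and `b` (from
#'   [align_hypnograms()]), or a character vector of first-rating labels
#'   when `b` is given.
#' @param b optional character vector of second-rating labels.
#' @return A `confusion_matrix`.
#' @export
stage_confusion <- function(pairs, b = NULL) {
  if (!is.null(b)) {
    pairs <- data.frame(a = as.character(pairs), b = as.character(b),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("a", "b") %in% names(pairs)))
  if (length(pairs$a) != length(pairs$b)) {
    stop_earsleep("ratings have different lengths", "earsleep_validation_error")
  }
  validate_stage_labels(pairs$a, "rating-A")
  validate_stage_labels(pairs$b, "rating-B")
  tab <- table(factor(pairs$a, levels = sleep_stages()),
               factor(pairs$b, levels = sleep_stages()))
  m <- matrix(as.integer(tab), nrow = length(sleep_stages()),
              dimnames = list(sleep_stages(), sleep_stages()))
  as_confusion_matrix(m)
}

landis_koch_breaks <- data.frame(
  upper = c(0, 0.20, 0.40, 0.60, 0.80, 1),
  label = c("poor", "slight", "fair", "moderate", "substantial",
            "almost perfect"),
  stringsAsFactors = FALSE
)

#' Landis-Koch verbal agreement category
#'
#' Maps a kappa value onto the conventional verbal scale:
#' `<= 0` poor, `(0, 0.20]` slight, `(0.20, 0.40]` fair, `(0.40, 0.60]`
#' moderate, `(0.60, 0.80]` substantial, `(0.80, 1]` almost perfect.
#'
#' @param kappa a kappa value in `[-1, 1]`.
#' @return The category label as a string.
#' @examples
#' landis_koch_label(0.67)  # "substantial"
#' @export
landis_koch_label <- function(kappa) {
  if (!is_scalar_number(kappa) || kappa < -1 || kappa > 1) {
    stop_earsleep("kappa must lie in [-1, 1]", "earsleep_validation_error")
  }
  landis_koch_breaks$label[[which(kappa <= landis_koch_breaks$upper)[1L]]]
}

#' Cohen's kappa with asymptotic standard error
#'
#' Chance-corrected agreement between two categorical ratings:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement
#' `po = trace / n` and chance agreement
#' `pe = sum_i (rowsum_i * colsum_i) / n^2`. The standard error is the
#' asymptotic delta-method variance for unweighted kappa
#' (Fleiss, Cohen & Everitt):
#' `var = (A + B - C) / (n (1 - pe)^2)` with
#' `A = sum_i p_ii (1 - (p_i. + p_.i)(1 - kappa))^2`,
#' `B = (1 - kappa)^2 sum_{i != j} p_ij (p_.i + p_j.)^2`,
#' `C = (kappa - pe (1 - kappa))^2`.
#'
#' @param m a `confusion_matrix`, or any labeled square count matrix
#'   accepted by [as_confusion_matrix()], or a plain square numeric
#'   matrix (e.g. a collapsed 2 x 2 table).
#' @return An `agreement_result`: list with `kappa`, `se`, `po`, `pe`,
#'   `n` and the Landis-Koch `label`.
#' @examples
#' m <- diag(10, 6)
#' dimnames(m) <- list(sleep_stages(), sleep_stages())
#' cohen_kappa(m)$kappa  # 1
#' @export
cohen_kappa <- function(m) {
  if (is.matrix(m) && !inherits(m, "confusion_matrix") &&
      !is.null(rownames(m)) && all(rownames(m) %in% sleep_stages())) {
    m <- as_confusion_matrix(m)
  }
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_earsleep("need a square count matrix", "earsleep_validation_error")
  }
  m <- unclass(m)
  n <- sum(m)
  if (n <= 0) {
    stop_earsleep("confusion matrix has zero total", "earsleep_validation_error")
  }
  p <- m / n
  po <- sum(diag(p))
  prow <- rowSums(p)
  pcol <- colSums(p)
  pe <- sum(prow * pcol)
  if (1 - pe <= 0) {
    stop_earsleep("degenerate margins (pe = 1): kappa undefined",
                  "earsleep_undefined_kappa_error")
  }
  kappa <- (po - pe) / (1 - pe)
  k <- nrow(p)
  A <- sum(diag(p) * (1 - (prow + pcol) * (1 - kappa))^2)
  B <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) B <- B + p[i, j] * (pcol[i] + prow[j])^2
    }
  }
  B <- (1 - kappa)^2 * B
  C <- (kappa - pe * (1 - kappa))^2
  var_k <- (A + B - C) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  structure(
    list(kappa = kappa, se = se, po = po, pe = pe, n = n,
         label = landis_koch_label(max(min(kappa, 1), -1))),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f +/- %.3f (%s agreement)\n",
              x$kappa, x$se, x$label))
  cat(sprintf("po = %.4f, pe = %.4f, n = %d epochs\n", x$po, x$pe,
              as.integer(x$n)))
  invisible(x)
}

#' One-vs-rest Cohen's kappa for a single stage
#'
#' Collapses the 6-class confusion matrix to a 2 x 2 table of the
#' requested stage against everything else (artifact epochs count as
#' "rest"), then applies [cohen_kappa()]. This is the per-stage
#' reliability used to compare how well individual stages are
#' reproduced.
#'
#' @param m a confusion matrix accepted by [as_confusion_matrix()].
#' @param stage one of [sleep_stages()].
#' @return An `agreement_result` for the collapsed table.
#' @export
one_vs_rest_kappa <- function(m, stage) {
  m <- as_confusion_matrix(m)
  if (!stage %in% sleep_stages()) {
    stop_earsleep(sprintf("unknown stage '%s'", stage),
                  "earsleep_validation_error")
  }
  if (sum(m[stage, ]) + sum(m[, stage]) == 0) {
    stop_earsleep(sprintf("stage '%s' absent from both ratings: kappa undefined",
                          stage), "earsleep_undefined_kappa_error")
  }
  a <- m[stage, stage]
  b <- sum(m[stage, ]) - a
  cc <- sum(m[, stage]) - a
  d <- sum(m) - a - b - cc
  collapsed <- matrix(as.numeric(c(a, b, cc, d)), nrow = 2, byrow = TRUE,
                      dimnames = list(c(stage, "rest"), c(stage, "rest")))
  cohen_kappa(collapsed)
}

#' Paired one-tailed t-test on per-participant kappas
#'
#' Tests whether condition `b` agrees better than condition `a` across
#' participants: paired t statistic on the per-participant differences,
#' one-tailed p-value for the alternative `mean(b) > mean(a)`. When the
#' differences have zero variance the statistic is undefined; the
#' boundary case of identical inputs (all differences zero) returns the
#' no-effect limit `t = 0, p = 0.5`, any other constant difference
#' raises a degenerate-test error.
#'
#' @param kappas_a,kappas_b numeric vectors of per-participant kappas,
#'   paired by participant, length >= 2.
#' @return List with `t`, `p`, `df` and `mean_diff` (`mean(b - a)`).
#' @export
paired_t_onetailed <- function(kappas_a, kappas_b) {
  if (length(kappas_a) != length(kappas_b) || length(kappas_a) < 2L) {
    stop_earsleep("need paired vectors of equal length >= 2",
                  "earsleep_validation_error")
  }
  d <- kappas_b - kappas_a
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    if (all(d == 0)) {
      return(list(t = 0, p = 0.5, df = length(d) - 1L, mean_diff = 0))
    }
    stop_earsleep("differences are constant (zero variance): t undefined",
                  "earsleep_degenerate_test_error")
  }
  ht <- stats::t.test(kappas_b, kappas_a, paired = TRUE,
                      alternative = "greater")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d))
}

#' Bundled reference confusion matrices
#'
#' The three published expert-scorer confusion matrices shipped with the
#' package as worked-example inputs: the Fpz+EOG test-retest comparison
#' (two ratings of the same frontal-reference data, two years apart) and
#' the comparisons of the Fpz+EOG reference rating against the
#' ear-electrode-only (`cEEGrid`) and ear-plus-EOG (`cEEGrid+EOG`)
#' ratings, pooled over participants.
#'
#' @return Named list of three `confusion_matrix` objects:
#'   `test_retest`, `fpz_vs_ceegrid`, `fpz_vs_ceegrid_eog`.
#' @examples
#' cm <- study_confusion_matrices()
#' cohen_kappa(cm$test_retest)
#' @export
study_confusion_matrices <- function() {
  files <- c(
    test_retest        = "confusion_fpz_test_retest.csv",
    fpz_vs_ceegrid     = "confusion_fpz_vs_ceegrid.csv",
    fpz_vs_ceegrid_eog = "confusion_fpz_vs_ceegrid_eog.csv"
  )
  lapply(files, function(f) {
    path <- system.file("extdata", f, package = "earsleep", mustWork = TRUE)
    read_confusion_csv(path)
  })
}
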