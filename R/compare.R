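#' Per-electrode DTF profile
#'
#' Collapses a (pruned) band-mean DTF matrix to one scalar per electrode:
#' `inflow` is the mean of the electrode's off-diagonal row (significant
#' inflow shares), `outflow` the mean of its off-diagonal column, and
#' `total` the mean of the two.
#'
#' @param pruned a [prune()] result or a plain `dtf` object.
#' @param mode one of `"total"` (default), `"inflow"`, `"outflow"`.
#' @param subject_id,condition optional labels carried along for reporting.
#' @return An object of class `electrode_profile`: named numeric vector of
#'   per-electrode values with attributes `mode`, `band`, `subject_id`,
#'   `condition`.
#' @export
electrode_profile <- function(pruned, mode = c("total", "inflow", "outflow"),
                              subject_id = NA_character_,
                              condition = NA_character_) {
  mode <- match.arg(mode)
  if (inherits(pruned, "dtf_pruned")) {
    bm <- pruned$dtf$band_mean; band <- pruned$band; labels <- pruned$labels
  } else if (inherits(pruned, "dtf")) {
    bm <- pruned$band_mean; band <- pruned$band; labels <- pruned$labels
  } else stop("`pruned` must be a dtf or dtf_pruned object")
  N <- nrow(bm)
  off <- bm
  diag(off) <- NA
  inflow <- rowMeans(off, na.rm = TRUE)
  outflow <- colMeans(off, na.rm = TRUE)
  vals <- switch(mode, inflow = inflow, outflow = outflow,
                 total = (inflow + outflow) / 2)
  names(vals) <- if (is.null(labels)) as.character(seq_len(N)) else labels
  structure(vals, mode = mode, band = band, subject_id = subject_id,
            condition = condition, class = "electrode_profile")
}

#' @export
print.electrode_profile <- function(x, ...) {
  cat(sprintf("<electrode_profile> mode %s, band %g-%g Hz\n",
              attr(x, "mode"), attr(x, "band")[1], attr(x, "band")[2]))
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, 4))
  invisible(x)
}

profiles_to_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (inherits(profiles, "electrode_profile")) profiles <- list(profiles)
  sapply(profiles, function(p) unclass(p)[names(profiles[[1]])])
}

#' Electrode-wise two-sample comparison of DTF profiles
#'
#' Compares, electrode by electrode, a reference group of profiles against a
#' second sample (e.g. eight control subjects against one patient's
#' per-epoch profiles, or a pre- against a post-treatment condition).  Under
#' `test = "auto"` each electrode uses a two-sample t-test when both sides
#' pass a Shapiro-Wilk normality check at 0.05, and Wilcoxon's rank-sum test
#' otherwise.
#'
#' @param group list of [electrode_profile()]s (or electrodes x observations
#'   matrix) for the reference side.
#' @param subject same for the comparison side (for a single subject, its
#'   per-epoch profiles).
#' @param alpha selection threshold on the (possibly adjusted) p-value.
#' @param test `"auto"` (default), `"t"`, or `"wilcoxon"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `comparison_report`: data.frame with one row
#'   per common electrode (`electrode`, `statistic`, `p`, `test`,
#'   `direction` -- subject `"lower"`/`"higher"` than group -- and
#'   `selected`), with attributes `alpha`, `selected_electrodes`.
#' @export
compare_profiles <- function(group, subject, alpha = 0.05,
                             test = c("auto", "t", "wilcoxon"),
                             adjust = c("none", "BH")) {
  test <- match.arg(test); adjust <- match.arg(adjust)
  G <- profiles_to_matrix(group)
  S <- profiles_to_matrix(subject)
  common <- intersect(rownames(G), rownames(S))
  if (length(common) == 0) stop("no common electrode labels between the two sides")
  if (ncol(G) < 3 || ncol(S) < 3)
    stop("need at least 3 observations per side per electrode (got ",
         ncol(G), " and ", ncol(S), ")")
  rows <- lapply(common, function(el) {
    x <- G[el, ]; y <- S[el, ]
    use <- test
    if (test == "auto") {
      normal <- function(v) {
        if (length(unique(v)) < 3) return(FALSE)
        stats::shapiro.test(v)$p.value > 0.05
      }
      use <- if (normal(x) && normal(y)) "t" else "wilcoxon"
    }
    ht <- if (use == "t") stats::t.test(x, y)
          else suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(electrode = el, statistic = unname(ht$statistic),
               p = ht$p.value, test = use,
               direction = if (stats::median(y) < stats::median(x))
                 "lower" else "higher",
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (adjust == "BH") rep$p <- stats::p.adjust(rep$p, method = "BH")
  rep$selected <- rep$p <= alpha
  attr(rep, "alpha") <- alpha
  attr(rep, "adjust") <- adjust
  attr(rep, "selected_electrodes") <- rep$electrode[rep$selected]
  class(rep) <- c("comparison_report", class(rep))
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  sel <- attr(x, "selected_electrodes")
  cat(sprintf("<comparison_report> %d of %d electrodes selected at alpha = %g\n",
              length(sel), nrow(x), attr(x, "alpha")))
  if (length(sel)) cat("  selected:", paste(sel, collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

#' Write a comparison report to CSV + JSON
#'
#' @param report a [compare_profiles()] result.
#' @param csv_path output CSV path; a JSON summary is written next to it.
#' @return `csv_path`, invisibly.
#' @export
write_comparison <- function(report, csv_path) {
  utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(alpha = attr(report, "alpha"), adjust = attr(report, "adjust"),
         selected = attr(report, "selected_electrodes")),
    sub("\\.csv$", ".json", csv_path), auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
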