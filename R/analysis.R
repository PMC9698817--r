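#' Convert an intensity profile to proportions
#'
#' Divides every intensity by the profile total so the values sum to 1;
#' the natural scale for comparing products whose overall intensity mass
#' differs. An all-zero profile has no defined proportions and is an error.
#'
#' @param p An [odor_profile()].
#' @return An [odor_profile()] of the same layer whose values sum to 1.
#' @export
to_proportions <- function(p) {
  stopifnot(inherits(p, "odor_profile"))
  total <- sum(as.numeric(p))
  if (total <= 0)
    stop("proportions are undefined for an all-zero profile", call. = FALSE)
  odor_profile(profile_values(p) / total, layer = attr(p, "layer"))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Compare the attribute proportions of two products
#'
#' For each label, tests whether the label's share of total intensity mass
#' differs between the two products, with a two-proportion z-test on the
#' intensity masses treated as counts (intensities rounded half away from
#' zero; successes = the label's mass, trials = the product's total mass).
#' The test is computed as `stats::prop.test(correct = FALSE)`, whose
#' chi-squared statistic is the square of the two-sided z statistic. When
#' the pooled proportion is degenerate (0 or 1 in both products) the
#' proportions are identical and p is reported as 1.
#'
#' No multiple-testing correction is applied by default (per-label flags
#' are raw, as in classic per-attribute significance marks); `correct =
#' "holm"` switches on a Holm adjustment. The test is count-based, so
#' doubling both totals at fixed shares can only make p-values smaller —
#' significance depends on the intensity scale, not just the shares.
#'
#' @param pa,pb [odor_profile()]s of the same layer and label set, each with
#'   positive total.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param correct `"none"` (default) or `"holm"`.
#' @return An object of class `profile_comparison`: a data frame with
#'   columns `label`, `prop_a`, `prop_b`, `p_value`, `significant`, plus
#'   attributes `alpha` and `correct`.
#' @export
compare_products <- function(pa, pb, alpha = 0.05,
                             correct = c("none", "holm")) {
  correct <- match.arg(correct)
  stopifnot(inherits(pa, "odor_profile"), inherits(pb, "odor_profile"))
  if (!identical(attr(pa, "layer"), attr(pb, "layer")))
    stop("profiles are from different layers", call. = FALSE)
  if (!setequal(names(pa), names(pb)))
    stop("profiles have mismatched label sets", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  labels <- names(pa)
  xa <- round_half_away(as.numeric(pa))
  xb <- round_half_away(as.numeric(pb[labels]))
  na <- sum(xa)
  nb <- sum(xb)
  if (na <= 0 || nb <= 0)
    stop("both profiles must have positive total intensity", call. = FALSE)
  pvals <- vapply(seq_along(labels), function(i) {
    two_prop_p(xa[i], na, xb[i], nb)
  }, numeric(1))
  if (correct == "holm") pvals <- stats::p.adjust(pvals, method = "holm")
  out <- data.frame(label = labels,
                    prop_a = xa / na,
                    prop_b = xb / nb,
                    p_value = pvals,
                    significant = pvals < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, alpha = alpha, correct = correct,
            class = c("profile_comparison", "data.frame"))
}

two_prop_p <- function(x1, n1, x2, n2) {
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) return(1)  # zero variance, equal shares
  res <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
  unname(res$p.value)
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> alpha = %g, correction = %s\n",
              attr(x, "alpha"), attr(x, "correct")))
  df <- as.data.frame(x)
  df$flag <- ifelse(df$significant, "*", "")
  print(df[c("label", "prop_a", "prop_b", "p_value", "flag")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a comparison to CSV and a plain-text report
#'
#' @param cmp A [compare_products()] result.
#' @param csv_path,report_path Output file paths; either may be `NULL` to
#'   skip that output.
#' @return `cmp`, invisibly.
#' @export
write_comparison <- function(cmp, csv_path = NULL, report_path = NULL) {
  stopifnot(inherits(cmp, "profile_comparison"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(cmp), csv_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(report_path)) {
    lines <- c(
      sprintf("Profile comparison (alpha = %g, correction = %s)",
              attr(cmp, "alpha"), attr(cmp, "correct")),
      "",
      sprintf("%-24s %8s %8s %10s %s", "label", "prop_a", "prop_b",
              "p_value", ""),
      sprintf("%-24s %8.4f %8.4f %10.4g %s", cmp$label, cmp$prop_a,
              cmp$prop_b, cmp$p_value, ifelse(cmp$significant, "*", "")))
    writeLines(lines, report_path)
  }
  invisible(cmp)
}
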