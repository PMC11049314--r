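#' Dice overlap coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`. Two empty masks are defined to overlap
#' perfectly (Dice 1).
#'
#' @param a,b Logical arrays of identical shape.
#' @return Overlap fraction in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have identical shape")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Compare paired volume measurements from two methods
#'
#' Pearson correlation (two-sided), paired t-test and Bland-Altman limits of
#' agreement (mean difference +/- 1.96 SD) for paired measurements such as
#' per-subject lesion volumes from two segmentation methods.
#'
#' @param a,b Paired numeric vectors (n >= 3, same names if named).
#' @return A `comparison_report` list with `n`, `pearson_r`, `pearson_p`,
#'   `paired_t_p`, `bland_altman` (`mean_diff`, `lo`, `hi`) and the inputs.
#' @export
compare_volumes <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("a and b must cover the same classes")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- stats::cor.test(a, b, alternative = "two.sided", method = "pearson")
  tt <- stats::t.test(a, b, paired = TRUE)
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d)
  structure(list(n = length(a),
                 pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
                 paired_t = unname(tt$statistic), paired_t_p = tt$p.value,
                 bland_altman = c(mean_diff = md, lo = md - 1.96 * sdd,
                                  hi = md + 1.96 * sdd),
                 a = a, b = b),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison of %d paired volumes\n", x$n))
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  paired t  = %.3f (p = %.3g)\n", x$paired_t, x$paired_t_p))
  cat(sprintf("  Bland-Altman: %.3f [%.3f, %.3f]\n",
              x$bland_altman["mean_diff"], x$bland_altman["lo"],
              x$bland_altman["hi"]))
  invisible(x)
}

#' Per-class Dice between two label volumes
#'
#' @param a,b `label_volume` objects with compatible class codes.
#' @param classes Class indices to compare (default: all classes of `a`).
#' @return Named numeric vector of Dice coefficients.
#' @export
label_dice <- function(a, b, classes = seq_along(a$class_names)) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  out <- vapply(classes, function(k) dice(a$labels == k, b$labels == k),
                numeric(1))
  stats::setNames(out, a$class_names[classes])
}
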