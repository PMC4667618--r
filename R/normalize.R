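#' Fit a pairwise normalization model
#'
#' Fits one of the two pairwise wild-type/mutant normalization schemes used
#' for fold-change comparisons:
#'
#' * `"trimmed_mean"`: the ratio of 10% trimmed means (symmetric trim, by
#'   count with floor rounding, as in `mean(trim =)`) is used to scale
#'   *the larger library only* (larger by total counts) down onto the
#'   smaller one.
#' * `"linear_regression"`: ordinary least squares of the mutant counts on
#'   the wild-type counts (wild type is the reference); the line's
#'   equation is then inverted to normalize the mutant,
#'   `mut' = (mut - intercept) / slope`.
#'
#' Both schemes are the identity on identical pairs.
#'
#' @param counts_wt,counts_mut Equal-length non-negative count vectors over
#'   identical regions.
#' @param kind `"trimmed_mean"` or `"linear_regression"`.
#' @param trim Trim fraction per tail for the trimmed mean, in `[0, 0.5)`.
#' @return An object of class `pair_norm`.
#' @seealso [apply_normalization()]
#' @export
fit_pair_normalization <- function(counts_wt, counts_mut,
                                   kind = c("trimmed_mean", "linear_regression"),
                                   trim = 0.10) {
  kind <- match.arg(kind)
  stopifnot(length(counts_wt) == length(counts_mut), length(counts_wt) >= 2,
            trim >= 0, trim < 0.5)
  if (any(counts_wt < 0) || any(counts_mut < 0)) abort("counts must be non-negative")
  out <- list(kind = kind, trim = trim, scale = 1, side = NA_character_,
              slope = NA_real_, intercept = NA_real_)
  if (kind == "trimmed_mean") {
    side <- if (sum(counts_mut) >= sum(counts_wt)) "mut" else "wt"
    larger <- if (side == "mut") counts_mut else counts_wt
    smaller <- if (side == "mut") counts_wt else counts_mut
    tl <- mean(larger, trim = trim)
    if (identical(larger, smaller) || isTRUE(all.equal(larger, smaller))) {
      out$scale <- 1
    } else {
      if (tl <= 0) abort("trimmed mean of the larger library is not positive")
      out$scale <- mean(smaller, trim = trim) / tl
    }
    out$side <- side
  } else {
    fit <- lm(counts_mut ~ counts_wt)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    if (is.na(slope) || slope <= 0) {
      abort("degenerate pair: regression slope is not positive")
    }
    out$slope <- slope
    out$intercept <- intercept
  }
  structure(out, class = "pair_norm")
}

#' Apply a pairwise normalization model
#'
#' @param counts_wt,counts_mut Count vectors as passed to
#'   [fit_pair_normalization()] (or new counts over the same regions).
#' @param model A `pair_norm` object.
#' @return A tibble with normalized `wt` and `mut` columns.
#' @export
apply_normalization <- function(counts_wt, counts_mut, model) {
  stopifnot(inherits(model, "pair_norm"),
            length(counts_wt) == length(counts_mut))
  if (model$kind == "trimmed_mean") {
    if (model$side == "mut") {
      tibble(wt = as.numeric(counts_wt), mut = counts_mut * model$scale)
    } else {
      tibble(wt = counts_wt * model$scale, mut = as.numeric(counts_mut))
    }
  } else {
    tibble(wt = as.numeric(counts_wt),
           mut = (counts_mut - model$intercept) / model$slope)
  }
}

#' @export
print.pair_norm <- function(x, ...) {
  if (x$kind == "trimmed_mean") {
    cat("<pair_norm> trimmed mean (trim ", x$trim, "): scale ",
        signif(x$scale, 4), " applied to the ", x$side, " library\n", sep = "")
  } else {
    cat("<pair_norm> linear regression: mut ~ ", signif(x$intercept, 4), " + ",
        signif(x$slope, 4), " * wt\n", sep = "")
  }
  invisible(x)
}

#' @rdname fit_pair_normalization
#' @param x A `pair_norm` object.
#' @param ... Unused.
#' @export
tidy.pair_norm <- function(x, ...) {
  if (x$kind == "trimmed_mean") {
    tibble(term = c("scale", "side"),
           estimate = c(x$scale, NA),
           value = c(NA_character_, x$side))
  } else {
    tibble(term = c("intercept", "slope"),
           estimate = c(x$intercept, x$slope),
           value = NA_character_)
  }
}

#' @rdname fit_pair_normalization
#' @export
glance.pair_norm <- function(x, ...) {
  tibble(kind = x$kind, trim = x$trim, scale = x$scale, side = x$side,
         slope = x$slope, intercept = x$intercept)
}

#' Quantile-normalize binned tracks
#'
#' Transforms two or more binned tracks over identical bins so that their
#' sorted value vectors coincide (each distribution is replaced by the
#' mean of the order statistics across tracks), the standard
#' quantile-normalization reference. Delegates to
#' `limma::normalizeQuantiles()`.
#'
#' @param tracks A list of binned-track tibbles over identical bins, or a
#'   numeric matrix with one column per track.
#' @return The same structure with normalized values.
#' @export
quantile_normalize <- function(tracks) {
  if (is.matrix(tracks)) {
    stopifnot(ncol(tracks) >= 2)
    return(limma::normalizeQuantiles(tracks))
  }
  stopifnot(is.list(tracks), length(tracks) >= 2)
  ref <- tracks[[1]][c("chrom", "start", "end")]
  for (t in tracks[-1]) {
    if (!identical(t$chrom, ref$chrom) || !identical(t$start, ref$start)) {
      abort("all tracks must be binned over identical bins")
    }
  }
  m <- vapply(tracks, function(t) t$value, numeric(nrow(ref)))
  norm <- limma::normalizeQuantiles(m)
  for (i in seq_along(tracks)) tracks[[i]]$value <- norm[, i]
  tracks
}
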