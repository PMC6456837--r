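#' Low thinning of a tree list
#'
#' Low thinning (thinning from below) removes the smallest-diameter trees.
#' The removal threshold is the arithmetic mean diameter of the stand minus
#' `offset` cm; every tree with diameter strictly below the threshold is
#' removed, boundary trees are retained. With the default 2 cm offset a
#' homogeneous stand is left untouched.
#'
#' @param trees Data frame of tree records with columns `diameter` (cm) and
#'   optionally `height` (m), one row per tree.
#' @param offset Distance below the mean diameter that marks a tree for
#'   removal, cm (>= 0); default 2.
#' @return A list of class `thinning_result`:
#'   \describe{
#'     \item{retained, removed}{the two partitions of `trees`}
#'     \item{threshold}{removal threshold, cm}
#'     \item{removed_fraction}{share of stems removed (diagnostic)}
#'   }
#' @examples
#' trees <- data.frame(diameter = c(12, 12, 12, 12, 6))
#' low_thin(trees, offset = 2)  # removes the 6 cm tree
#' @export
low_thin <- function(trees, offset = 2.0) {
  if (is.null(trees$diameter) || nrow(trees) == 0L) {
    stop("need a non-empty tree list with a 'diameter' column",
         call. = FALSE)
  }
  if (any(!is.finite(trees$diameter)) || any(trees$diameter <= 0)) {
    stop("tree diameters must be positive", call. = FALSE)
  }
  if (!is.finite(offset) || offset < 0) {
    stop("offset must be non-negative", call. = FALSE)
  }
  threshold <- mean(trees$diameter) - offset
  cut <- trees$diameter < threshold
  res <- list(retained = trees[!cut, , drop = FALSE],
              removed = trees[cut, , drop = FALSE],
              threshold = threshold,
              removed_fraction = mean(cut))
  class(res) <- "thinning_result"
  res
}

#' @export
print.thinning_result <- function(x, ...) {
  cat("Low thinning: threshold ", round(x$threshold, 2), " cm; removed ",
      nrow(x$removed), " of ", nrow(x$removed) + nrow(x$retained),
      " trees (", round(100 * x$removed_fraction, 1), "%)\n", sep = "")
  invisible(x)
}

#' Stems removed between two stand tables
#'
#' For every age present in both a pre-thinning and a post-thinning stand
#' table, the number of stems removed per hectare is the stocking
#' difference `n_pre - n_post`.
#'
#' @param pre,post [stand_table()]s sharing at least one age.
#' @return Data frame with columns `age` and `removed` (stems ha^-1), with
#'   attributes `min` and `max` giving the range over ages.
#' @examples
#' pre  <- stand_table(18, 1550, 11.3, 7.5, 0.72)
#' post <- stand_table(18, 1460, 12.0, 8.3, 0.72)
#' removed_stems(pre, post)  # 90 stems/ha
#' @export
removed_stems <- function(pre, post) {
  validate_stand_table(pre)
  validate_stand_table(post)
  common <- intersect(pre$age, post$age)
  if (length(common) == 0L) {
    stop("the two stand tables share no common age", call. = FALSE)
  }
  out <- data.frame(
    age = common,
    removed = pre$n[match(common, pre$age)] - post$n[match(common, post$age)]
  )
  attr(out, "min") <- min(out$removed)
  attr(out, "max") <- max(out$removed)
  out
}

#' MAI gain from thinning at a given age
#'
#' Relative change of mean annual increment between a pre-thinning and a
#' post-thinning stand table at one age,
#' `100 * (MAI_post - MAI_pre) / MAI_pre` percent. By default the MAIs are
#' recomputed from the stand attributes via [growth_table()]; published MAI
#' values can be supplied instead through `mai_pre`/`mai_post` (useful when
#' a printed volume cell is known to disagree with the form-factor
#' formula).
#'
#' @param pre,post [stand_table()]s containing `age`.
#' @param age Age (years) at which to evaluate the contrast.
#' @param mai_pre,mai_post Optional externally supplied MAI values
#'   overriding the recomputed ones.
#' @return MAI gain, percent.
#' @export
mai_gain <- function(pre, post, age, mai_pre = NULL, mai_post = NULL) {
  if (is.null(mai_pre)) {
    g <- growth_table(pre)
    if (!age %in% g$age) stop("age ", age, " not in pre table", call. = FALSE)
    mai_pre <- g$mai[g$age == age]
  }
  if (is.null(mai_post)) {
    g <- growth_table(post)
    if (!age %in% g$age) stop("age ", age, " not in post table", call. = FALSE)
    mai_post <- g$mai[g$age == age]
  }
  100 * (mai_post - mai_pre) / mai_pre
}

#' Age-wise thinning contrast of two stand tables
#'
#' Combines [removed_stems()] and [mai_gain()] over all common ages of a
#' pre/post-thinning pair: stems removed, both MAIs (recomputed), the MAI
#' gain in percent and the fraction of stems removed.
#'
#' @param pre,post [stand_table()]s sharing at least one age.
#' @return Data frame with one row per common age and columns `age`,
#'   `n_pre`, `n_post`, `stems_removed`, `removed_fraction`, `mai_pre`,
#'   `mai_post`, `mai_gain_pct`.
#' @export
thinning_contrast <- function(pre, post) {
  rem <- removed_stems(pre, post)
  gpre <- growth_table(pre)
  gpost <- growth_table(post)
  ipre <- match(rem$age, gpre$age)
  ipost <- match(rem$age, gpost$age)
  data.frame(
    age = rem$age,
    n_pre = gpre$n[ipre],
    n_post = gpost$n[ipost],
    stems_removed = rem$removed,
    removed_fraction = rem$removed / gpre$n[ipre],
    mai_pre = gpre$mai[ipre],
    mai_post = gpost$mai[ipost],
    mai_gain_pct = 100 * (gpost$mai[ipost] - gpre$mai[ipre]) / gpre$mai[ipre]
  )
}
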