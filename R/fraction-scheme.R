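#' Define the fractionation scheme of an experiment
#'
#' A fractionation scheme names the five differential-centrifugation profile
#' fractions (SILAC ratio columns) and the three global fractions
#' (nuclear/organellar/cytosolic, "N"/"O"/"C"), and carries the relative
#' protein yields of each fraction. Yields are used as weights when ratio
#' profiles are converted to normalized "proportion pelleted" profiles, and
#' when N/O/C intensities are converted to global distribution profiles.
#'
#' Defaults follow a typical HeLa differential-pelleting experiment: profile
#' fractions named after centrifugation speeds ("3K" ... "78.4K") with equal
#' yields, and global yields of 0.32 (nuclear), 0.20 (organellar) and 0.48
#' (cytosolic).
#'
#' @param profile_fractions Character vector of exactly five profile fraction
#'   labels, in centrifugation order.
#' @param profile_yields Named (or positionally matched) numeric vector of
#'   relative protein yields of the profile fractions; must sum to 1.
#' @param global_fractions Character vector of three global fraction labels.
#' @param global_yields Relative protein yields of the global fractions;
#'   must sum to 1.
#'
#' @return An object of class `fraction_scheme`: a list with elements
#'   `profile_fractions`, `profile_yields`, `global_fractions`,
#'   `global_yields`.
#' @export
#'
#' @examples
#' sc <- fraction_scheme()
#' sc$profile_fractions
fraction_scheme <- function(profile_fractions = c("3K", "5.4K", "12.2K", "24K", "78.4K"),
                            profile_yields = rep(0.2, 5),
                            global_fractions = c("N", "O", "C"),
                            global_yields = c(N = 0.32, O = 0.20, C = 0.48)) {
  if (length(profile_fractions) != 5L) {
    abort("`profile_fractions` must contain exactly 5 labels.")
  }
  if (length(global_fractions) != 3L) {
    abort("`global_fractions` must contain exactly 3 labels.")
  }
  profile_yields <- .match_yields(profile_yields, profile_fractions, "profile_yields")
  global_yields <- .match_yields(global_yields, global_fractions, "global_yields")
  structure(
    list(
      profile_fractions = as.character(profile_fractions),
      profile_yields = profile_yields,
      global_fractions = as.character(global_fractions),
      global_yields = global_yields
    ),
    class = "fraction_scheme"
  )
}

.match_yields <- function(yields, labels, what) {
  if (length(yields) != length(labels)) {
    abort(sprintf("`%s` must have one value per fraction.", what))
  }
  if (!is.null(names(yields)) && all(nzchar(names(yields)))) {
    if (!setequal(names(yields), labels)) {
      abort(sprintf("Names of `%s` must match the fraction labels.", what))
    }
    yields <- yields[labels]
  } else {
    names(yields) <- labels
  }
  if (any(yields <= 0)) abort(sprintf("`%s` must be positive.", what))
  if (abs(sum(yields) - 1) > 1e-9) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", what, sum(yields)))
  }
  yields
}

#' @export
print.fraction_scheme <- function(x, ...) {
  cat("<fraction_scheme>\n")
  cat("  profile:", paste(sprintf("%s (%.3f)", x$profile_fractions, x$profile_yields),
    collapse = ", "
  ), "\n")
  cat("  global: ", paste(sprintf("%s (%.3f)", x$global_fractions, x$global_yields),
    collapse = ", "
  ), "\n")
  invisible(x)
}

# Column names of the five ratio columns of a profile tibble.
profile_cols <- function(scheme) paste0("ratio_", scheme$profile_fractions)

# Extract an n x 5 numeric matrix (rownames = protein_id) from a profile tibble.
profile_matrix <- function(tbl, scheme) {
  cols <- profile_cols(scheme)
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(
      "Profile table lacks fraction column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  m <- as.matrix(tbl[, cols])
  rownames(m) <- tbl$protein_id
  storage.mode(m) <- "double"
  m
}
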