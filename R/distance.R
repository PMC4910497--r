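#' Restricted Damerau-Levenshtein (optimal string alignment) distance
#'
#' Minimum number of single-character insertions, deletions, substitutions
#' and adjacent transpositions converting one string into the other, in the
#' optimal-string-alignment (OSA) variant: no substring is edited twice, so
#' the triangle inequality is not guaranteed — the variant used by
#' TaxaMatch-style name matching. Symmetric; zero iff the strings are equal.
#'
#' With \code{per_token = TRUE} the strings are split on spaces and, when
#' the token counts agree, token distances (genus vs genus, epithet vs
#' epithet) are computed separately and summed; with differing token counts
#' it falls back to the whole-string distance.
#'
#' @param a,b character vectors (recycled to common length). Intended input
#'   is [match_key()]-normalized canonical strings, but any strings work.
#' @param max_tolerance optional early-exit bound: distances known to
#'   exceed it are reported as \code{max_tolerance + 1}. Values above 6
#'   (the practical ceiling for name matching) are allowed but pointless.
#' @param allow_transposition count adjacent transpositions as one edit
#'   (default \code{TRUE}); \code{FALSE} gives plain Levenshtein.
#' @param per_token compare space-separated tokens separately and sum.
#' @return integer vector of distances.
#' @examples
#' dl_distance("dorsophila melanogaster", "drosophila melanogaster")
#' dl_distance("mumia", "rumia")
#' @export
dl_distance <- function(a, b, max_tolerance = NULL,
                        allow_transposition = TRUE, per_token = FALSE) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (k in seq_len(n)) {
    out[k] <- if (per_token) {
      ta <- strsplit(a[k], " ", fixed = TRUE)[[1]]
      tb <- strsplit(b[k], " ", fixed = TRUE)[[1]]
      if (length(ta) == length(tb) && length(ta) > 1L) {
        sum(mapply(osa_one, ta, tb,
                   MoreArgs = list(transpose = allow_transposition)))
      } else {
        osa_one(a[k], b[k], transpose = allow_transposition)
      }
    } else {
      osa_one(a[k], b[k], transpose = allow_transposition)
    }
  }
  if (!is.null(max_tolerance)) {
    max_tolerance <- as.integer(max_tolerance)
    out[out > max_tolerance] <- max_tolerance + 1L
  }
  out
}

# single-pair OSA dynamic programme
osa_one <- function(a, b, transpose = TRUE) {
  if (is.na(a) || is.na(b)) return(NA_integer_)
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  la <- length(sa)
  lb <- length(sb)
  if (la == 0L) return(lb)
  if (lb == 0L) return(la)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0L:la
  d[1L, ] <- 0L:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      v <- min(d[i, j + 1L] + 1L,      # deletion
               d[i + 1L, j] + 1L,      # insertion
               d[i, j] + cost)         # substitution
      if (transpose && i > 1L && j > 1L &&
          sa[i] == sb[j - 1L] && sa[i - 1L] == sb[j]) {
        v <- min(v, d[i - 1L, j - 1L] + 1L)
      }
      d[i + 1L, j + 1L] <- v
    }
  }
  d[la + 1L, lb + 1L]
}

#' Edit-distance matching parameters
#'
#' Bundles the knobs of fuzzy matching: the edit-distance tolerance
#' (capped at 6, the observed ceiling at which a correct match has ever
#' been found), whether adjacent transpositions count as single edits, and
#' whether distances are computed per token.
#'
#' @param max_tolerance maximum edit distance searched (default 1; up to 6).
#' @param allow_transposition see [dl_distance()].
#' @param per_token see [dl_distance()].
#' @return a list of class \code{"gn_match_params"}.
#' @export
match_params <- function(max_tolerance = 1L, allow_transposition = TRUE,
                         per_token = FALSE) {
  max_tolerance <- as.integer(max_tolerance)
  if (is.na(max_tolerance) || max_tolerance < 0L || max_tolerance > 6L) {
    stop("'max_tolerance' must be an integer in [0, 6]")
  }
  structure(
    list(max_tolerance = max_tolerance,
         allow_transposition = isTRUE(allow_transposition),
         per_token = isTRUE(per_token)),
    class = "gn_match_params"
  )
}
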