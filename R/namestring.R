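#' Normalize a raw name-string
#'
#' Applies Unicode NFC normalization, trims leading/trailing whitespace and
#' collapses internal runs of whitespace to single spaces. Distinct
#' non-whitespace codepoints are never mapped together: a Cyrillic
#' \code{"а"} stays distinct from a Latin \code{"a"}, so visually
#' identical lookalike strings remain distinguishable downstream (this
#' matters for identifier minting, see [gn_uuid()]).
#'
#' @param x character vector of raw name-strings.
#' @return character vector of the same length, NFC-normalized, trimmed,
#'   with single internal spaces.
#' @examples
#' normalize_name("  Bison   bison ")
#' @export
normalize_name <- function(x) {
  if (length(x) == 0L) return(character())
  x <- enc2utf8(as.character(x))
  x <- stringi::stri_trans_nfc(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

# Hybrid multiplication-sign lookalikes seen in real sources: the true
# multiplication sign, Cyrillic kha (upper/lower) and Latin x/X used as a
# standalone sign.
.hybrid_signs <- c("×", "х", "Х")

#' Detect hybrid notation in a name-string
#'
#' Recognizes the hybrid multiplication sign in its common encoding variants
#' (\code{×}, Cyrillic \code{х}/\code{Х}, and a standalone
#' Latin \code{x}/\code{X} between name-like tokens) as well as the leading
#' sign of a named "natural hybrid".
#'
#' @param x character vector of name-strings.
#' @return a tibble with columns \code{name}, \code{hybrid_flag} (logical)
#'   and \code{components} (list of character vectors). A hybrid formula
#'   between two names yields two components; a natural hybrid (leading
#'   sign, or an infix sign inside a single binomial) yields one.
#' @examples
#' detect_hybrid("Magnolia heptapeta x Magnolia quinquepeta")
#' detect_hybrid("x Cuprocyparis leylandii")
#' @export
detect_hybrid <- function(x) {
  x <- normalize_name(x)
  res <- lapply(x, detect_hybrid_one)
  tibble::tibble(
    name = x,
    hybrid_flag = vapply(res, `[[`, logical(1), "hybrid_flag"),
    components = lapply(res, `[[`, "components")
  )
}

detect_hybrid_one <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(list(hybrid_flag = FALSE, components = character()))
  }
  sign_class <- paste0("[xX", paste(.hybrid_signs, collapse = ""), "]")
  lead_re <- paste0("^", sign_class, "\\s+")
  if (stringi::stri_detect_regex(x, lead_re)) {
    comp <- stringi::stri_replace_first_regex(x, lead_re, "")
    return(list(hybrid_flag = TRUE, components = comp))
  }
  infix_re <- paste0("\\s", sign_class, "\\s")
  if (stringi::stri_detect_regex(x, infix_re)) {
    parts <- stringi::stri_trim_both(
      stringi::stri_split_regex(x, infix_re)[[1]]
    )
    parts <- parts[nzchar(parts)]
    name_like <- vapply(
      parts,
      function(p) stringi::stri_detect_regex(p, "^[A-Z][a-zà-ÿ-]+"),
      logical(1)
    )
    if (length(parts) >= 2L && all(name_like)) {
      return(list(hybrid_flag = TRUE, components = unname(parts)))
    }
    # single-name hybrid written with an infix sign (e.g. "Malus x domestica")
    return(list(hybrid_flag = TRUE, components = paste(parts, collapse = " ")))
  }
  list(hybrid_flag = FALSE, components = character())
}
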