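#' Canonical forms of parsed names
#'
#' Reduces parsed names to their latinized canonical versions.
#' The \emph{complete} canonical retains all latinized elements (subgenus,
#' rank markers); the \emph{standard} canonical retains only the elements
#' the nomenclatural codes require: genus or uninomial, the specific epithet
#' and any infraspecific epithets. For a bare subgeneric combination such as
#' \code{"Aaleniella (Danocythere)"} the standard canonical is the subgenus
#' name. Authorship, years, annotations, strain/acronym tails and hybrid
#' signs are dropped from both forms.
#'
#' @param parsed a tibble from [gn_parse()], or a character vector of raw
#'   name-strings (parsed internally).
#' @param on_unparseable \code{"error"} (default) to signal that no
#'   canonical exists for an unparseable input, or \code{"na"} to return
#'   \code{NA} fields for such rows.
#' @return a tibble with columns \code{complete}, \code{standard} and
#'   \code{match_key}.
#' @examples
#' gn_canonical("Aaleniella (Danocythere)")
#' gn_canonical("Anolis barkeri Schmidt, 1939")
#' @export
gn_canonical <- function(parsed, on_unparseable = c("error", "na")) {
  on_unparseable <- match.arg(on_unparseable)
  if (is.character(parsed)) parsed <- gn_parse(parsed)
  bad <- parsed$quality == "unparseable"
  if (any(bad) && on_unparseable == "error") {
    stop(
      "no canonical form exists for unparseable name-string(s): ",
      paste(utils::head(parsed$verbatim[bad], 3), collapse = ", ")
    )
  }
  n <- nrow(parsed)
  complete <- standard <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    if (bad[k]) next
    head_name <- if (!is.na(parsed$genus[k])) {
      parsed$genus[k]
    } else {
      parsed$uninomial[k]
    }
    infra <- parsed$infraspecific[[k]]
    sg <- parsed$subgenus[k]

    comp <- head_name
    if (parsed$candidatus_flag[k]) comp <- paste("Candidatus", comp)
    if (!is.na(sg)) comp <- paste0(comp, " (", sg, ")")
    if (!is.na(parsed$specific_epithet[k])) {
      comp <- paste(comp, parsed$specific_epithet[k])
    }
    if (nrow(infra)) {
      for (j in seq_len(nrow(infra))) {
        if (!is.na(infra$rank_marker[j])) {
          comp <- paste(comp, infra$rank_marker[j])
        }
        comp <- paste(comp, infra$epithet[j])
      }
    }
    complete[k] <- comp

    if (is.na(parsed$specific_epithet[k]) && !is.na(sg)) {
      # bare subgeneric combination: the standard form is the subgenus
      standard[k] <- sg
    } else {
      std <- c(head_name, parsed$specific_epithet[k], infra$epithet)
      standard[k] <- paste(std[!is.na(std)], collapse = " ")
    }
  }
  tibble::tibble(
    complete = complete,
    standard = standard,
    match_key = match_key(standard)
  )
}

#' Matching key of a canonical form
#'
#' Deterministic normalization of a standard canonical used for exact-key
#' and fuzzy matching: lower-cased, hyphens removed (so
#' \code{"Indigofera roseo-caerulea"} and \code{"Indigofera roseocaerulea"}
#' share one key), hybrid signs removed, and diacritics transliterated to
#' ASCII.
#'
#' @param standard character vector of standard canonical forms.
#' @return character vector of matching keys (\code{NA} propagates).
#' @examples
#' match_key("Indigofera roseo-caerulea")
#' @export
match_key <- function(standard) {
  x <- tolower(as.character(standard))
  x <- stringi::stri_replace_all_regex(
    x, paste0("[x]?[", paste(.hybrid_signs, collapse = ""), "]\\s*"), ""
  )
  x <- stringi::stri_replace_all_fixed(x, "-", "")
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  stringi::stri_trim_both(stringi::stri_replace_all_regex(x, "\\s+", " "))
}

# Orthographic fold used only inside fuzzy matching: interchangeable
# latinizations (i/y, ae/oe/e) and gender terminations (-us/-um/-a) are
# folded to one spelling so such variants cost less than a raw edit.
fold_key <- function(key) {
  x <- stringi::stri_replace_all_fixed(key, "y", "i")
  x <- stringi::stri_replace_all_fixed(x, "ae", "e")
  x <- stringi::stri_replace_all_fixed(x, "oe", "e")
  stringi::stri_replace_all_regex(x, "(u[ms])\\b", "a")
}
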