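#' Load pre-processing repair rules
#'
#' Reads an ordered list of regular-expression repair rules from YAML.
#' Each rule has an \code{id}, a PCRE \code{pattern}, a \code{replacement}
#' (which may use \code{\\L}/\code{\\U} case operators) and the
#' \code{flags} it sets when it fires. The packaged default covers the
#' recurring idiosyncrasies of uncurated sources: interpolated separators
#' (\code{_}, \code{0}, \code{X}) between genus and species elements,
#' trailing accession tokens, and capitalization damage.
#'
#' @param path path to a rules YAML file, or \code{NULL} for the packaged
#'   default.
#' @return a list of rules, each a list with \code{id}, \code{pattern},
#'   \code{replacement}, \code{flags}.
#' @export
gn_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "preprocess_rules.yaml", package = "gnkit")
  }
  if (!file.exists(path)) stop("rules file not found: ", path)
  r <- yaml::read_yaml(path)$rules
  if (is.null(r) || !length(r)) stop("rules file has no 'rules' list")
  for (rule in r) {
    if (is.null(rule$id) || is.null(rule$pattern)) {
      stop("every rule needs an 'id' and a 'pattern'")
    }
  }
  r
}

#' Rule-driven repair of idiosyncratic name-strings
#'
#' Applies the ordered repair rules to each input, logging which rules
#' fired. Strings that are exactly 10 characters after repair (the
#' abbreviation width seen in data-logging environments) are flagged
#' \code{truncated_suspect}; truncated names are deliberately \emph{not}
#' dictionary-expanded — recovery of the full epithet is left to fuzzy
#' matching downstream. A single all-lower-case token with no separator
#' ("corbulasulcata") cannot be split without a per-source dictionary and
#' is marked \code{unresolvable}.
#'
#' @param x character vector of raw name-strings.
#' @param rules ordered rule list from [gn_rules()]; packaged default when
#'   \code{NULL}.
#' @return a tibble with columns \code{original}, \code{repaired},
#'   \code{flags} (list of character vectors from \{\code{deconcatenated},
#'   \code{truncated_suspect}, \code{case_repaired}, \code{tail_stripped}\}),
#'   \code{rule_ids} (list) and \code{unresolvable} (logical).
#' @examples
#' gn_preprocess(c("Triticum_aestivum", "Danio0reri", "corbulasulcata"))
#' @export
gn_preprocess <- function(x, rules = NULL) {
  if (is.null(rules)) rules <- default_rules()
  if (!length(rules)) stop("'rules' must be a nonempty rule list")
  x <- as.character(x)
  orig <- normalize_name(x)
  n <- length(orig)
  repaired <- orig
  flags <- rep(list(character()), n)
  rule_ids <- rep(list(character()), n)

  # doubled separators ("Pan__Herm") are not simple genus-species
  # concatenations; without a per-source dictionary the reading is
  # ambiguous, so they are left unresolvable rather than guessed at
  ambiguous <- stringi::stri_detect_fixed(orig, "__")

  for (rule in rules) {
    new <- gsub(rule$pattern, rule$replacement %||% "", repaired, perl = TRUE)
    new[ambiguous] <- repaired[ambiguous]
    changed <- !is.na(new) & new != repaired
    if (any(changed)) {
      for (k in which(changed)) {
        flags[[k]] <- union(flags[[k]], unlist(rule$flags))
        rule_ids[[k]] <- c(rule_ids[[k]], rule$id)
      }
      repaired[changed] <- normalize_name(new[changed])
    }
  }

  unresolvable <- ambiguous |
    (!stringi::stri_detect_regex(repaired, "[A-ZÀ-ÖØ-Þ]") &
       !stringi::stri_detect_regex(repaired, "[\\s_0]") &
       nchar(repaired) > 0L &
       repaired == orig)
  # a 10-character repaired string that needed repair points at the
  # 10-character abbreviation convention
  trunc <- nchar(repaired) == 10L & repaired != orig
  for (k in which(trunc)) {
    flags[[k]] <- union(flags[[k]], "truncated_suspect")
  }
  for (k in which(unresolvable)) flags[[k]] <- character()

  tibble::tibble(
    original = orig, repaired = repaired, flags = flags,
    rule_ids = rule_ids, unresolvable = unresolvable
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_rules <- function() {
  if (is.null(the$rules)) the$rules <- gn_rules()
  the$rules
}
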