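#' Classify name-strings by their usefulness for interconnecting data
#'
#' Assigns every name-string to exactly one major class of a revised
#' usefulness scheme: clade-identifiable ranks (\code{clade_species},
#' \code{clade_genus}, \code{clade_infraspecies}, \code{clade_higher}),
#' \code{virus}, \code{common_name}, \code{hybrid}, \code{symbiont},
#' \code{negated}, or \code{not_useful} with a minor subclass
#' (\code{numbered}, \code{environmental}, \code{acronym},
#' \code{strain_surrogate}, \code{organelle}, \code{plasmid},
#' \code{molecular}, \code{abbreviated}, \code{no_genus},
#' \code{concatenated_unresolved}, \code{too_fuzzy}).
#'
#' Overlapping cues are resolved by a fixed priority: numbered strings,
#' then virus markers, hybrid notation, symbiont markers, negation
#' annotations, clade structure from the parse, the common-name heuristic,
#' and finally the not-useful subclasses. Virus must outrank clade because
#' virus strings routinely embed host binomials. \code{cf.}/\code{aff.}/
#' \code{nr.} negate the species but leave a usable genus, so such strings
#' demote to \code{clade_genus} rather than \code{negated} when the genus
#' parses.
#'
#' @param x character vector of raw name-strings.
#' @param vocab vocabulary from [gn_vocab()]; packaged default when
#'   \code{NULL}.
#' @param preprocess repair concatenations/case damage (via
#'   [gn_preprocess()]) before parsing. Default \code{TRUE}.
#' @return a tibble with columns \code{name}, \code{major}, \code{minor}
#'   (\code{NA} unless \code{major == "not_useful"}) and \code{evidence}
#'   (list of matched vocabulary terms / structural reasons).
#' @examples
#' gn_classify(c("RTBV", "Gambierodiscus aff toxicus",
#'               "environmental samples"))
#' @export
gn_classify <- function(x, vocab = NULL, preprocess = TRUE) {
  if (is.null(vocab)) vocab <- default_vocab()
  cl <- vocab$classifier
  x <- as.character(x)
  pre <- if (preprocess) gn_preprocess(x) else NULL
  rows <- lapply(seq_along(x), function(k) {
    classify_one(
      raw = normalize_name(x[k]),
      repaired = if (preprocess) pre$repaired[k] else normalize_name(x[k]),
      unresolvable = if (preprocess) pre$unresolvable[k] else FALSE,
      case_pre = if (preprocess) "case_repaired" %in% pre$flags[[k]] else FALSE,
      vocab = vocab, cl = cl
    )
  })
  tibble::tibble(
    name = normalize_name(x),
    major = vapply(rows, `[[`, character(1), "major"),
    minor = vapply(rows, `[[`, character(1), "minor"),
    evidence = lapply(rows, `[[`, "evidence")
  )
}

word_hits <- function(low, terms) {
  terms <- tolower(terms)
  hits <- terms[vapply(terms, function(t) {
    stringi::stri_detect_regex(
      low, paste0("\\b", stringi::stri_replace_all_regex(
        t, "([.\\\\+*?\\[\\]()^$|])", "\\\\$1"
      ), "\\b")
    )
  }, logical(1))]
  unname(hits)
}

classify_one <- function(raw, repaired, unresolvable, case_pre = FALSE,
                         vocab, cl) {
  res <- function(major, minor = NA_character_, evidence = character()) {
    list(major = major, minor = minor, evidence = evidence)
  }
  if (!nzchar(raw)) return(res("not_useful", "molecular", "empty string"))
  low <- tolower(raw)

  # numbered: leading digits fall outside the conventions of names
  if (stringi::stri_detect_regex(raw, "^[0-9]")) {
    return(res("not_useful", "numbered", "leading digit"))
  }

  # viruses: term, suffix, or terminal-V acronym
  vhit <- word_hits(low, cl$virus_terms)
  for (p in cl$virus_patterns) {
    m <- stringi::stri_extract_first_regex(raw, p)
    if (!is.na(m)) vhit <- c(vhit, m)
  }
  if (length(vhit)) return(res("virus", evidence = unique(vhit)))

  # hybrids: sign in any encoding, or the term itself
  hyb <- detect_hybrid_one(raw)
  if (hyb$hybrid_flag ||
      length(word_hits(low, c("hybrid", "hybridcultivar")))) {
    ev <- if (hyb$hybrid_flag) "hybrid sign" else "term 'hybrid'"
    return(res("hybrid", evidence = ev))
  }

  # symbionts: association terms and joins
  shit <- word_hits(low, cl$symbiont_terms)
  for (p in cl$symbiont_patterns) {
    m <- stringi::stri_extract_first_regex(raw, p)
    if (!is.na(m)) shit <- c(shit, m)
  }
  if (length(shit)) return(res("symbiont", evidence = unique(shit)))

  parsed <- gn_parse_one(repaired, vocab)
  ann <- parsed$annotations
  kinds <- ann$kind

  # negations: non/nec/not annotations negate outright; cf./aff./nr.
  # negate the species but may leave a usable genus
  if ("negation" %in% kinds) {
    return(res("negated", evidence = ann$token[kinds == "negation"]))
  }
  soft <- kinds %in% c("cf", "aff", "nr")
  if (any(soft)) {
    if (!is.na(parsed$genus) || !is.na(parsed$uninomial)) {
      return(res("clade_genus", evidence = c(
        ann$token[soft], "genus recoverable"
      )))
    }
    return(res("negated", evidence = ann$token[soft]))
  }

  # environmental screen: sample terms with no leading latinized taxon
  ehit <- word_hits(low, cl$environmental_terms)
  leading_cap <- stringi::stri_detect_regex(raw, "^[A-ZÀ-ÖØ-Þ][a-zà-öø-ÿ]")
  if (length(ehit) && !leading_cap) {
    return(res("not_useful", "environmental", ehit))
  }

  # organelle / plasmid / molecular context outranks an embedded binomial
  for (pair in list(
    c("organelle", "organelle_terms"),
    c("plasmid", "plasmid_terms"),
    c("molecular", "molecular_terms")
  )) {
    hit <- word_hits(low, cl[[pair[2]]])
    if (length(hit)) return(res("not_useful", pair[1], hit))
  }

  # a leading strain/isolate marker means the string is a surrogate, not
  # a name ("strain Royal Perth Hospital 13487")
  if (stringi::stri_detect_regex(low, "^(type )?(strain|str\\.|isolate)\\b")) {
    return(res("not_useful", "strain_surrogate", "leading strain marker"))
  }

  # vernacular vocabulary inside apparently latinized structure is a
  # stronger signal than the structure ("Lyme disease spirochete")
  chit <- word_hits(low, cl$common_words)
  if (length(chit)) return(res("common_name", evidence = chit))

  case_repaired <- parsed$case_repaired || case_pre

  # clade classes by the deepest identifiable latinized rank
  if (parsed$quality != "unparseable" && !case_repaired) {
    head_name <- if (!is.na(parsed$genus)) parsed$genus else parsed$uninomial
    head_suff <- cl$higher_rank_suffixes[vapply(
      cl$higher_rank_suffixes,
      function(s) stringi::stri_endswith_fixed(tolower(head_name), s),
      logical(1)
    )]
    if (length(head_suff)) {
      # "Sphingomonadaceae bacterium TPD06": a family-rank head outranks
      # pseudo-epithets that follow it
      return(res("clade_higher",
                 evidence = paste0("suffix -", head_suff[1])))
    }
    if (nrow(parsed$infraspecific)) {
      return(res("clade_infraspecies", evidence = "infraspecific epithet"))
    }
    if (!is.na(parsed$specific_epithet)) {
      return(res("clade_species", evidence = "binomial structure"))
    }
    u <- parsed$uninomial
    if (!is.na(u)) {
      suff <- cl$higher_rank_suffixes[vapply(
        cl$higher_rank_suffixes,
        function(s) stringi::stri_endswith_fixed(tolower(u), s),
        logical(1)
      )]
      if (u %in% cl$higher_rank_names || length(suff)) {
        return(res("clade_higher", evidence = c(
          if (length(suff)) paste0("suffix -", suff[1]) else u
        )))
      }
      return(res("clade_genus", evidence = "uninomial structure"))
    }
  }

  # common-name heuristic: natural-language structure or possessives
  # without latinized name structure
  possessive <- stringi::stri_detect_regex(raw, "'s\\b|’s\\b")
  function_words <- word_hits(low, c("of", "the", "and", "or", "with"))
  if (possessive ||
      (length(function_words) && parsed$quality == "unparseable")) {
    return(res("common_name", evidence = unique(c(
      if (possessive) "possessive", function_words
    ))))
  }

  # case-repaired parses that survived to here are still clade evidence
  if (parsed$quality != "unparseable" && case_repaired) {
    if (!is.na(parsed$specific_epithet)) {
      return(res(
        if (nrow(parsed$infraspecific)) "clade_infraspecies"
        else "clade_species",
        evidence = "binomial structure (case repaired)"
      ))
    }
  }

  # not-useful subclasses
  if (length(ehit)) return(res("not_useful", "environmental", ehit))
  if (stringi::stri_detect_regex(raw, "\\b(strain|str\\.)\\b") ||
      stringi::stri_detect_regex(
        raw, paste0("\\b(", paste(cl$strain_collection_codes, collapse = "|"),
                    ")\\b[ :]?[A-Za-z0-9-]*[0-9]")
      )) {
    return(res("not_useful", "strain_surrogate", "strain/collection code"))
  }
  if (stringi::stri_detect_regex(raw, "^[A-Z][a-z]{0,2}\\.? ?[a-z]{3,}$")) {
    return(res("not_useful", "abbreviated", "abbreviated genus"))
  }
  if (unresolvable) {
    minor <- if (nchar(raw) > 12L) "concatenated_unresolved" else "no_genus"
    return(res("not_useful", minor, "unsplittable lower-case token"))
  }
  if (stringi::stri_detect_regex(raw, "[A-Z]{2,}|[0-9]")) {
    return(res("not_useful", "acronym", "code-like token"))
  }
  res("not_useful", "acronym", "no identifiable structure")
}
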