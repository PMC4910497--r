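#' Parse scientific name-strings into semantic components
#'
#' Decomposes raw name-strings into genus/uninomial, subgenus, specific and
#' infraspecific epithets (with their rank markers), authorship, annotations
#' (\code{cf.}, \code{aff.}, \code{sp.}, negations, ...) and an unparsed
#' tail. Parsing is total: it never fails, it degrades. Every string gets a
#' parse \code{quality} of \code{"clean"} (everything interpreted),
#' \code{"with_tail"} (a trailing remainder could not be interpreted) or
#' \code{"unparseable"} (no latinized name structure found at all).
#'
#' Rank interpretation is positional: one latinized token is a uninomial,
#' two are genus + specific epithet, three or more add infraspecific
#' epithets. Rank markers from the configured vocabulary (\code{ssp.},
#' \code{var.}, \code{f.}, \code{morph.}, ...) attach to the epithet that
#' follows them. A lower-case recovery pass re-tries an uncapitalized
#' genus with its first letter capitalized and flags the repair in
#' \code{case_repaired}.
#'
#' @param x character vector of raw name-strings.
#' @param vocab vocabulary list from [gn_vocab()]; the packaged default is
#'   used when \code{NULL}.
#' @return a tibble with one row per input and columns \code{verbatim},
#'   \code{normalized}, \code{uninomial}, \code{genus}, \code{subgenus},
#'   \code{specific_epithet}, \code{infraspecific} (list of tibbles with
#'   \code{rank_marker}, \code{epithet}), \code{authorship} (list),
#'   \code{annotations} (list of tibbles with \code{kind}, \code{token}),
#'   \code{hybrid_flag}, \code{candidatus_flag}, \code{case_repaired},
#'   \code{tail} and \code{quality}.
#' @examples
#' gn_parse("Bison bison athabascae")
#' gn_parse("Carex scirpoidea Michx. ssp. convoluta (Kük.) Dunlop")
#' @export
gn_parse <- function(x, vocab = NULL) {
  if (is.null(vocab)) vocab <- default_vocab()
  x <- as.character(x)
  rows <- lapply(x, gn_parse_one, vocab = vocab)
  tibble::tibble(
    verbatim = x,
    normalized = vapply(rows, `[[`, character(1), "normalized"),
    uninomial = vapply(rows, `[[`, character(1), "uninomial"),
    genus = vapply(rows, `[[`, character(1), "genus"),
    subgenus = vapply(rows, `[[`, character(1), "subgenus"),
    specific_epithet = vapply(rows, `[[`, character(1), "specific_epithet"),
    infraspecific = lapply(rows, `[[`, "infraspecific"),
    authorship = lapply(rows, `[[`, "authorship"),
    annotations = lapply(rows, `[[`, "annotations"),
    hybrid_flag = vapply(rows, `[[`, logical(1), "hybrid_flag"),
    candidatus_flag = vapply(rows, `[[`, logical(1), "candidatus_flag"),
    case_repaired = vapply(rows, `[[`, logical(1), "case_repaired"),
    tail = vapply(rows, `[[`, character(1), "tail"),
    quality = vapply(rows, `[[`, character(1), "quality")
  )
}

empty_infra <- function() {
  tibble::tibble(rank_marker = character(), epithet = character())
}

empty_annotations <- function() {
  tibble::tibble(kind = character(), token = character())
}

blank_parse <- function(norm) {
  list(
    normalized = norm, uninomial = NA_character_, genus = NA_character_,
    subgenus = NA_character_, specific_epithet = NA_character_,
    infraspecific = empty_infra(), authorship = NULL,
    annotations = empty_annotations(), hybrid_flag = FALSE,
    candidatus_flag = FALSE, case_repaired = FALSE,
    tail = norm, quality = "unparseable"
  )
}

# --- token predicates ------------------------------------------------------

LATIN_LOWER <- "a-zà-öø-ÿ"
LATIN_UPPER <- "A-ZÀ-ÖØ-Þ"

is_cap_word <- function(tok) {
  stringi::stri_detect_regex(
    tok,
    sprintf("^[%s][%s]+(-[%s%s][%s]*)*$",
            LATIN_UPPER, LATIN_LOWER, LATIN_UPPER, LATIN_LOWER, LATIN_LOWER)
  )
}

is_lower_epithet <- function(tok) {
  nchar(tok) >= 2L && stringi::stri_detect_regex(
    tok, sprintf("^[%s]+(-[%s]+)*$", LATIN_LOWER, LATIN_LOWER)
  )
}

AUTHOR_PARTICLES <- c(
  "von", "van", "de", "der", "den", "du", "del", "della", "le", "la",
  "ter", "ten", "zur", "zu", "dos", "das", "da"
)
AUTHOR_CONNECTORS <- c("&", "et", "and", "al.", "al", "in")

year_value <- function(tok) {
  m <- stringi::stri_match_first_regex(
    tok, "^[\\[(]?([0-9]{4})[\\])]?[.,]?$"
  )[, 2]
  if (is.na(m)) return(NA_integer_)
  y <- as.integer(m)
  if (y >= 1700L && y <= 2100L) y else NA_integer_
}

is_year_token <- function(tok) !is.na(year_value(tok))

is_bracketed_year <- function(tok) {
  stringi::stri_detect_regex(tok, "^\\[[0-9]{4}\\][.,]?$")
}

is_author_word <- function(tok) {
  tok <- sub(",$", "", tok)
  if (tok %in% AUTHOR_PARTICLES || tok %in% AUTHOR_CONNECTORS) return(TRUE)
  # capitalized token, allowing initials, abbreviations, hyphens,
  # apostrophes and all-caps house styles ("POWELL", "Hand.-Mazz.")
  nzchar(tok) && stringi::stri_detect_regex(
    tok,
    sprintf("^[%s][%s%s'.’-]*$", LATIN_UPPER, LATIN_UPPER, LATIN_LOWER)
  ) && !stringi::stri_detect_regex(tok, "[0-9]")
}

strip_trailing_comma <- function(tok) sub(",$", "", tok)

# --- annotation lookup -----------------------------------------------------

annotation_kind <- function(tok, vocab) {
  low <- tolower(tok)
  for (kind in names(vocab$annotations)) {
    if (low %in% vocab$annotations[[kind]]) return(kind)
  }
  NA_character_
}

# --- authorship segment ----------------------------------------------------

# Parses a flat run of author tokens (no parentheses) into authors, year and
# ex-authors. "A ex B" records A as ex_authors per botanical convention.
parse_author_run <- function(toks) {
  authors <- character()
  ex_authors <- character()
  year <- NA_integer_
  bracketed <- FALSE
  current <- character()
  flush_author <- function() {
    if (length(current)) {
      authors <<- c(authors, paste(current, collapse = " "))
      current <<- character()
    }
  }
  for (tok in toks) {
    had_comma <- grepl(",$", tok)
    t <- strip_trailing_comma(tok)
    if (is_year_token(t)) {
      if (is.na(year)) {
        year <- year_value(t)
        bracketed <- bracketed || is_bracketed_year(t)
      }
      flush_author()
    } else if (t %in% c("&", "et", "and")) {
      flush_author()
    } else if (t %in% c("al.", "al")) {
      if (length(current)) current <- c(current, "al.")
      flush_author()
    } else if (t == "ex") {
      flush_author()
      ex_authors <- c(ex_authors, authors)
      authors <- character()
    } else if (t %in% AUTHOR_PARTICLES || t == "in") {
      current <- c(current, t)
    } else {
      current <- c(current, t)
      if (had_comma) flush_author()
    }
  }
  flush_author()
  list(authors = authors, year = year, ex_authors = ex_authors,
       bracketed = bracketed)
}

# --- the single-name parser ------------------------------------------------

gn_parse_one <- function(raw, vocab = default_vocab()) {
  norm <- normalize_name(raw)
  out <- blank_parse(norm)
  if (is.na(norm) || !nzchar(norm)) {
    out$tail <- ""
    out$normalized <- if (is.na(norm)) "" else norm
    return(out)
  }

  ann <- empty_annotations()
  add_ann <- function(kind, token) {
    ann <<- rbind(ann, tibble::tibble(kind = kind, token = token))
  }

  # whole-string annotation patterns (nom. illeg., sensu lato, ...)
  for (kind in names(vocab$annotation_patterns)) {
    hit <- stringi::stri_extract_first_regex(
      norm, vocab$annotation_patterns[[kind]]
    )
    if (!is.na(hit)) add_ann(kind, hit)
  }

  work <- norm

  # hybrid notation: parse the first component, remainder joins the tail
  hyb <- detect_hybrid_one(work)
  hybrid_tail <- character()
  if (hyb$hybrid_flag) {
    out$hybrid_flag <- TRUE
    if (length(hyb$components)) {
      work <- hyb$components[[1]]
      if (length(hyb$components) > 1L) {
        hybrid_tail <- hyb$components[-1]
      }
    }
  }

  # Candidatus prefix (interim prokaryote names)
  if (stringi::stri_detect_regex(work, "^Candidatus\\s+")) {
    out$candidatus_flag <- TRUE
    work <- stringi::stri_replace_first_regex(work, "^Candidatus\\s+", "")
  }

  # bracketed genus: "[Bacillus] sp." — uncertainty convention for
  # prokaryotes; genus is recovered and the brackets recorded
  m <- stringi::stri_match_first_regex(
    work, sprintf("^\\[([%s][%s]+)\\]\\s*", LATIN_UPPER, LATIN_LOWER)
  )
  if (!is.na(m[1, 1])) {
    add_ann("nom_status", m[1, 1])
    work <- paste0(
      m[1, 2], " ",
      stringi::stri_replace_first_fixed(work, m[1, 1], "")
    )
    work <- normalize_name(work)
  }

  toks <- stringi::stri_split_fixed(work, " ")[[1]]
  toks <- toks[nzchar(toks)]

  # leading annotation tokens ("not Brucella ovis ...", "cf. Bison")
  while (length(toks) > 1L && !is.na(annotation_kind(toks[1], vocab))) {
    add_ann(annotation_kind(toks[1], vocab), toks[1])
    toks <- toks[-1]
  }
  n <- length(toks)
  if (n == 0L) return(out)

  # head token: the genus / uninomial candidate, with a lower-case
  # recovery pass
  head_tok <- toks[1]
  if (!is_cap_word(head_tok)) {
    recovered <- paste0(
      toupper(substr(head_tok, 1, 1)), substring(head_tok, 2)
    )
    if (is_cap_word(recovered) && nchar(recovered) >= 3L) {
      head_tok <- recovered
      out$case_repaired <- TRUE
    } else {
      out$annotations <- ann
      return(out)  # unparseable: tail already set to the whole string
    }
  }
  if (nchar(head_tok) < 2L) {
    out$annotations <- ann
    return(out)
  }

  i <- 2L
  subgenus <- NA_character_
  if (i <= n) {
    sg <- stringi::stri_match_first_regex(
      toks[i], sprintf("^\\(([%s][%s]+)\\)$", LATIN_UPPER, LATIN_LOWER)
    )[, 2]
    if (!is.na(sg)) {
      subgenus <- sg
      i <- i + 1L
    }
  }

  rank_set <- vocab$rank_markers
  greek_set <- vocab$greek_rank_letters
  single_set <- vocab$single_letter_ranks

  epithets <- empty_infra()
  pending_rank <- NA_character_
  author_segments <- list()
  tail_start <- NA_integer_
  phase <- "epithet"

  is_rank_marker <- function(tok, have_binomial) {
    low <- tolower(tok)
    if (low %in% rank_set) return(TRUE)
    # Greek letters and bare single letters act as infrasubspecific rank
    # markers only once a full binomial has been read
    have_binomial && (tok %in% greek_set || low %in% single_set)
  }

  # collect one authorship segment starting at position i; returns
  # list(segment or NULL, next_i); NULL segment means "not authorship"
  read_author_segment <- function(i) {
    seg <- list(
      combination_authors = character(), combination_year = NA_integer_,
      basionym_authors = character(), basionym_year = NA_integer_,
      ex_authors = character(), bracketed_year = FALSE,
      verbatim = character()
    )
    start <- i
    # optional parenthesized basionym group
    if (i <= n && stringi::stri_startswith_fixed(toks[i], "(")) {
      j <- i
      while (j <= n && !stringi::stri_endswith_fixed(toks[j], ")") &&
             !stringi::stri_endswith_fixed(toks[j], "),") &&
             !stringi::stri_endswith_fixed(toks[j], ").")) {
        j <- j + 1L
      }
      if (j > n) return(list(segment = NULL, next_i = start))
      group <- toks[i:j]
      inner <- stringi::stri_replace_all_regex(
        paste(group, collapse = " "), "^\\(|\\)[.,]?$", ""
      )
      inner_toks <- stringi::stri_split_fixed(inner, " ")[[1]]
      ok <- vapply(inner_toks, function(t) {
        is_author_word(t) || is_year_token(t)
      }, logical(1))
      if (!length(inner_toks) || !all(ok)) {
        return(list(segment = NULL, next_i = start))
      }
      run <- parse_author_run(inner_toks)
      seg$basionym_authors <- run$authors
      seg$basionym_year <- run$year
      seg$bracketed_year <- seg$bracketed_year || run$bracketed
      seg$verbatim <- c(seg$verbatim, group)
      i <- j + 1L
    }
    # flat run of author tokens / connectors / years
    flat <- character()
    while (i <= n) {
      tok <- toks[i]
      if (is_rank_marker(tok, TRUE) && !tolower(tok) %in% c("nat", "race")) {
        break
      }
      if (!is.na(annotation_kind(tok, vocab))) break
      if (is_author_word(tok) || is_year_token(tok) ||
          tok %in% c("f.", "f", "fil.", "filius")) {
        flat <- c(flat, tok)
        i <- i + 1L
      } else {
        break
      }
    }
    if (length(flat)) {
      run <- parse_author_run(flat)
      # reject an all-caps "author" with no year: those are collection /
      # accession codes (CCUG, JCM, ...), not authorships
      allcaps <- length(run$authors) > 0L && all(
        stringi::stri_detect_regex(run$authors, "^[A-Z]{2,}$")
      )
      if (allcaps && is.na(run$year)) {
        i <- i - length(flat)
      } else {
        seg$combination_authors <- run$authors
        seg$combination_year <- run$year
        seg$ex_authors <- c(seg$ex_authors, run$ex_authors)
        seg$bracketed_year <- seg$bracketed_year || run$bracketed
        seg$verbatim <- c(seg$verbatim, flat)
      }
    }
    if (!length(seg$verbatim)) return(list(segment = NULL, next_i = start))
    list(segment = seg, next_i = i)
  }

  while (i <= n) {
    tok <- toks[i]
    have_binomial <- nrow(epithets) >= 1L
    if (is_rank_marker(tok, have_binomial)) {
      pending_rank <- tok
      phase <- "epithet"
      i <- i + 1L
      next
    }
    kind <- annotation_kind(tok, vocab)
    if (!is.na(kind)) {
      add_ann(kind, tok)
      i <- i + 1L
      next
    }
    if (phase == "epithet" && is_lower_epithet(tok) &&
        !tolower(tok) %in% AUTHOR_CONNECTORS &&
        !tok %in% AUTHOR_PARTICLES) {
      epithets <- rbind(
        epithets,
        tibble::tibble(rank_marker = pending_rank, epithet = tok)
      )
      pending_rank <- NA_character_
      i <- i + 1L
      next
    }
    if (is_author_word(tok) || stringi::stri_startswith_fixed(tok, "(")) {
      res <- read_author_segment(i)
      if (!is.null(res$segment)) {
        author_segments <- c(author_segments, list(res$segment))
        phase <- "author"
        i <- res$next_i
        next
      }
    }
    tail_start <- i
    break
  }

  tail_tokens <- if (!is.na(tail_start)) toks[tail_start:n] else character()
  if (!is.na(pending_rank)) {
    tail_tokens <- c(pending_rank, tail_tokens)  # marker with no epithet
    pending_rank <- NA_character_
  }
  tail_tokens <- c(tail_tokens, hybrid_tail)
  out$tail <- paste(tail_tokens, collapse = " ")

  if (nrow(epithets) >= 1L) {
    out$genus <- head_tok
    out$specific_epithet <- epithets$epithet[1]
    out$infraspecific <- epithets[-1, , drop = FALSE]
  } else {
    out$uninomial <- head_tok
  }
  out$subgenus <- subgenus

  if (length(author_segments)) {
    # the last segment carries the combination (and basionym) of record;
    # earlier segments (mid-name authorships of higher-rank elements) are
    # preserved in the verbatim record
    last <- author_segments[[length(author_segments)]]
    verb <- unlist(lapply(author_segments, `[[`, "verbatim"))
    basio <- Filter(function(s) length(s$basionym_authors) > 0L,
                    author_segments)
    if (!length(last$basionym_authors) && length(basio)) {
      last$basionym_authors <- basio[[1]]$basionym_authors
      last$basionym_year <- basio[[1]]$basionym_year
    }
    last$verbatim <- paste(verb, collapse = " ")
    out$authorship <- last
  }

  out$annotations <- ann
  out$quality <- if (nzchar(out$tail)) "with_tail" else "clean"
  out
}
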