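#' Fuzzy candidate search against an indexed target set
#'
#' Returns every target whose matching key lies within \code{max_tolerance}
#' edits of the query key, sorted by (distance, target). Ties at equal
#' distance are all returned — multi-target matches are real and must be
#' surfaced, not silently resolved. Candidates are pre-filtered by length
#' band; a first-letter mismatch is allowed whenever the tolerance admits
#' one edit, so names that lost their leading character ("chneumon
#' dorsalis") can still be recovered. Interchangeable latinizations
#' (i/y, ae/e, gender terminations) are folded before the comparison so
#' they cost less than a raw edit.
#'
#' @param query a single matching key (see [match_key()]).
#' @param target_keys character vector of target matching keys.
#' @param params a [match_params()] object.
#' @return a tibble with columns \code{target} (index into
#'   \code{target_keys}), \code{key} and \code{distance}, sorted by
#'   distance then key.
#' @examples
#' fuzzy_candidates("mumia",
#'   c("cumia", "mimia", "mucia", "mukia", "numia", "rumia", "bison"),
#'   match_params(1))
#' @export
fuzzy_candidates <- function(query, target_keys, params = match_params()) {
  stopifnot(length(query) == 1L)
  tol <- params$max_tolerance
  len_ok <- abs(nchar(target_keys) - nchar(query)) <= tol
  first_ok <- substr(target_keys, 1, 1) == substr(query, 1, 1) | tol >= 1L
  idx <- which(len_ok & first_ok & !is.na(target_keys))
  if (!length(idx)) {
    return(tibble::tibble(target = integer(), key = character(),
                          distance = integer()))
  }
  raw_d <- dl_distance(query, target_keys[idx],
                       allow_transposition = params$allow_transposition,
                       per_token = params$per_token)
  fold_d <- dl_distance(fold_key(query), fold_key(target_keys[idx]),
                        allow_transposition = params$allow_transposition,
                        per_token = params$per_token)
  # folding may reduce the distance ("taeniatus" ~ "taeniata") but a raw
  # difference always costs at least one edit
  d <- pmin(raw_d, pmax(fold_d, as.integer(raw_d > 0L)))
  keep <- d <= tol
  out <- tibble::tibble(
    target = idx[keep], key = target_keys[idx][keep],
    distance = as.integer(d[keep])
  )
  out[order(out$distance, out$key), ]
}

#' Cross-map a source checklist against a target checklist
#'
#' For every source record, attempts a hierarchy of match tiers against the
#' target and reports the first tier with at least one hit:
#' \enumerate{
#'   \item \code{exact} — the full raw name-strings are identical;
#'   \item \code{canonical_exact} — the standard-canonical matching keys
#'     are identical;
#'   \item \code{canonical_fuzzy} — keys within edit distance 1;
#'   \item \code{canonical_fuzzy} at distance 2..\code{max_tolerance};
#'   \item \code{partial_canonical} — infraspecific epithets stripped,
#'     then key-exact;
#'   \item \code{partial_canonical_fuzzy} — the stripped key, fuzzily;
#'   \item \code{genus_part} — the genus alone matches a target genus;
#'   \item \code{none}.
#' }
#' Full-name evidence is preferred over truncation, and genus-only matching
#' is the last resort before giving up. Each result carries the match
#' category, all tied targets, the edit distance, a calibrated confidence
#' (see [gn_confidence()]), the human-check flag (confidence at or below
#' 0.5) and a homonym alert when the matched canonical is on the supplied
#' homonym list.
#'
#' @param source,target data frames with columns \code{id} and \code{name}
#'   (a character vector is accepted and given ordinal ids). Source ids
#'   must be unique.
#' @param params a [match_params()] object.
#' @param homonyms character vector of standard canonicals known to be
#'   homonyms, or \code{NULL} for the packaged default list.
#' @param weights score weights from [score_weights()].
#' @param preprocess repair source names with [gn_preprocess()] first.
#' @return a tibble with one row per source record: \code{source_id},
#'   \code{source_name}, \code{category}, \code{edit_distance} (\code{NA}
#'   for non-fuzzy tiers), \code{targets} (list of tibbles with
#'   \code{target_id}, \code{target_name}), \code{n_targets},
#'   \code{points}, \code{confidence}, \code{needs_human_check},
#'   \code{homonym_alert}.
#' @export
gn_crossmap <- function(source, target, params = match_params(),
                        homonyms = NULL, weights = score_weights(),
                        preprocess = FALSE) {
  source <- as_records(source)
  target <- as_records(target)
  if (anyDuplicated(source$id)) stop("duplicate source ids")
  if (is.null(homonyms)) homonyms <- default_homonyms()

  src_names <- source$name
  if (preprocess) src_names <- gn_preprocess(src_names)$repaired

  tp <- gn_parse(target$name)
  tc <- gn_canonical(tp, on_unparseable = "na")
  sp <- gn_parse(src_names)
  sc <- gn_canonical(sp, on_unparseable = "na")

  t_partial_key <- partial_keys(tp, tc)
  t_genus_key <- genus_keys(tp)

  no_target <- nrow(target) == 0L

  rows <- vector("list", nrow(source))
  for (k in seq_len(nrow(source))) {
    hit <- NULL
    category <- "none"
    ed <- NA_integer_

    if (!no_target) {
      # tier 1: exact full string
      idx <- which(target$name == source$name[k])
      if (length(idx)) {
        hit <- idx; category <- "exact"; ed <- 0L
      }
      # tier 2: canonical exact via match key
      if (is.null(hit) && !is.na(sc$match_key[k])) {
        idx <- which(tc$match_key == sc$match_key[k])
        if (length(idx)) {
          hit <- idx; category <- "canonical_exact"; ed <- 0L
        }
      }
      # tiers 3-4: canonical fuzzy at rising tolerance
      if (is.null(hit) && !is.na(sc$match_key[k]) &&
          params$max_tolerance >= 1L) {
        cand <- fuzzy_candidates(sc$match_key[k], tc$match_key, params)
        cand <- cand[cand$distance > 0L, ]
        if (nrow(cand)) {
          ed <- min(cand$distance)
          hit <- cand$target[cand$distance == ed]
          category <- "canonical_fuzzy"
        }
      }
      # tier 5: partial canonical (strip infraspecific epithets)
      pk <- partial_key_one(sp[k, ], sc[k, ])
      if (is.null(hit) && !is.na(pk)) {
        idx <- which(tc$match_key == pk | t_partial_key == pk)
        if (length(idx)) {
          hit <- idx; category <- "partial_canonical"; ed <- 0L
        }
      }
      # tier 6: partial canonical fuzzy
      if (is.null(hit) && !is.na(pk) && params$max_tolerance >= 1L) {
        cand <- fuzzy_candidates(pk, tc$match_key, params)
        cand <- cand[cand$distance > 0L, ]
        if (nrow(cand)) {
          ed <- min(cand$distance)
          hit <- cand$target[cand$distance == ed]
          category <- "partial_canonical_fuzzy"
        }
      }
      # tier 7: genus part
      gk <- genus_key_one(sp[k, ])
      if (is.null(hit) && !is.na(gk)) {
        idx <- which(t_genus_key == gk &
                       (is.na(tc$match_key) | tc$match_key == gk))
        if (length(idx)) {
          hit <- idx; category <- "genus_part"; ed <- NA_integer_
        }
      }
    }

    if (is.null(hit)) {
      rows[[k]] <- result_row(
        source$id[k], source$name[k], "none", NA_integer_,
        tibble::tibble(target_id = character(), target_name = character()),
        NA_real_, NA_real_, NA, FALSE
      )
      next
    }

    tgt <- tibble::tibble(
      target_id = target$id[hit], target_name = target$name[hit]
    )
    rank <- matched_rank_of(category, sp[k, ], tc$standard[hit])
    auth <- authorship_state_of(sp$authorship[[k]], tp$authorship[hit])
    conf <- gn_confidence(
      rank, auth,
      edit_distance = ifelse(is.na(ed), 0L, ed),
      multi_target = nrow(tgt) > 1L, weights = weights
    )
    homonym <- any(tc$standard[hit] %in% homonyms, na.rm = TRUE)
    rows[[k]] <- result_row(
      source$id[k], source$name[k], category,
      if (category %in% c("canonical_fuzzy", "partial_canonical_fuzzy"))
        ed else NA_integer_,
      tgt, conf$points, conf$confidence, conf$needs_human_check, homonym
    )
  }
  do.call(rbind, rows)
}

result_row <- function(id, name, category, ed, tgt, points, conf,
                       check, homonym) {
  tibble::tibble(
    source_id = id, source_name = name, category = category,
    edit_distance = ed, targets = list(tgt), n_targets = nrow(tgt),
    points = points, confidence = conf,
    needs_human_check = check, homonym_alert = homonym
  )
}

as_records <- function(x) {
  if (is.character(x)) {
    return(tibble::tibble(id = as.character(seq_along(x)), name = x))
  }
  if (!all(c("id", "name") %in% names(x))) {
    stop("records need 'id' and 'name' columns")
  }
  tibble::tibble(id = as.character(x$id), name = as.character(x$name))
}

partial_key_one <- function(p, cn) {
  if (is.na(p$genus) || is.na(p$specific_epithet) ||
      nrow(p$infraspecific[[1]]) == 0L) {
    return(NA_character_)
  }
  match_key(paste(p$genus, p$specific_epithet))
}

partial_keys <- function(parsed, canon) {
  vapply(seq_len(nrow(parsed)), function(k) {
    if (!is.na(parsed$genus[k]) && !is.na(parsed$specific_epithet[k])) {
      match_key(paste(parsed$genus[k], parsed$specific_epithet[k]))
    } else {
      NA_character_
    }
  }, character(1))
}

genus_key_one <- function(p) {
  g <- if (!is.na(p$genus)) p$genus else p$uninomial
  if (is.na(g)) NA_character_ else match_key(g)
}

genus_keys <- function(parsed) {
  g <- ifelse(is.na(parsed$genus), parsed$uninomial, parsed$genus)
  ifelse(is.na(g), NA_character_, match_key(g))
}

matched_rank_of <- function(category, sp_row, matched_standard) {
  if (category == "genus_part") return("uninomial")
  std <- matched_standard[!is.na(matched_standard)][1]
  ntok <- if (is.na(std)) {
    1L
  } else {
    length(strsplit(std, " ", fixed = TRUE)[[1]])
  }
  if (category %in% c("partial_canonical", "partial_canonical_fuzzy")) {
    ntok <- min(ntok, 2L)
  }
  if (ntok <= 1L) "uninomial" else if (ntok == 2L) "binomial"
  else "trinomial_plus"
}

authorship_state_of <- function(src_auth, tgt_auths) {
  if (is.null(src_auth)) return("absent")
  src <- author_surnames(src_auth)
  if (!length(src)) return("absent")
  states <- vapply(tgt_auths, function(a) {
    if (is.null(a)) return("absent")
    tgt <- author_surnames(a)
    if (!length(tgt)) return("absent")
    if (length(intersect(src, tgt))) "agrees" else "conflicts"
  }, character(1))
  if (any(states == "agrees")) return("agrees")
  if (any(states == "conflicts")) return("conflicts")
  "absent"
}

# comparable author tokens: surnames lower-cased, initials and years
# dropped, abbreviation periods removed
author_surnames <- function(auth) {
  nm <- c(auth$combination_authors, auth$basionym_authors)
  nm <- unlist(strsplit(nm, " ", fixed = TRUE))
  nm <- tolower(gsub("[.,]", "", nm))
  nm <- nm[nchar(nm) >= 3L & !nm %in% AUTHOR_PARTICLES]
  # abbreviated surnames compare by prefix: reduce to the first 3 letters
  unique(substr(nm, 1, 3))
}

default_homonyms <- function() {
  if (is.null(the$homonyms)) {
    path <- system.file("extdata", "homonyms.txt", package = "gnkit")
    the$homonyms <- if (nzchar(path)) readLines(path, warn = FALSE)
    else character()
  }
  the$homonyms
}

#' Profile of a cross-mapping run
#'
#' Category counts and the multi-target inflation of a [gn_crossmap()]
#' result: the ratio of total reported (source, target) pairs to the
#' number of source records with a match, minus one. Multi-target matches
#' inflate apparent overlap between checklists and the report must expose
#' that.
#'
#' @param results a tibble from [gn_crossmap()].
#' @return a list with \code{categories} (tibble of category, n) and
#'   \code{inflation} (numeric fraction, 0 when every match is single).
#' @export
crossmap_profile <- function(results) {
  tab <- table(factor(results$category, levels = c(
    "exact", "canonical_exact", "canonical_fuzzy", "partial_canonical",
    "partial_canonical_fuzzy", "genus_part", "none"
  )))
  matched <- results[results$category != "none", ]
  inflation <- if (nrow(matched)) {
    sum(matched$n_targets) / nrow(matched) - 1
  } else {
    0
  }
  list(
    categories = tibble::tibble(
      category = names(tab), n = as.integer(tab)
    ),
    inflation = inflation
  )
}
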