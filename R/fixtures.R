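#' Bundled list of valid binomial names
#'
#' A list of several hundred valid (or valid-looking) species binomials
#' spanning plants, animals, fungi and prokaryotes, shipped with the
#' package so that corruption/recovery experiments need no external
#' checklist.
#'
#' @return character vector of binomials.
#' @export
clean_binomials <- function() {
  path <- system.file("extdata", "clean_binomials.txt", package = "gnkit")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

corruption_operators <- c(
  "concat_underscore", "concat_zero", "concat_x", "truncate_10",
  "drop_leading_char", "strip_genus", "author_noise", "chresonym_swap",
  "misspell_ed_k", "case_mangle", "add_strain_tail", "add_acronym_tail"
)

author_pool <- c(
  "Smith, 1902", "L.", "(Linnaeus, 1758)", "Boettger, 1887",
  "Mertens, 1937", "Hook.f.", "Baker f.", "(Schmidt, 1939)",
  "Warnst.", "Bates, 1865", "Kollar, [1844]", "Ueki et al. 2006"
)

#' Apply one corruption operator to a clean name
#'
#' The deterministic core of the dirty-checklist generator: applies a
#' single named operator, emulating the pathologies of uncurated sources —
#' interpolated-separator concatenations, 10-character truncation, lost
#' leading characters, missing genera, authorship noise, chresonyms,
#' seeded misspellings, case damage, and strain/acronym tails.
#'
#' @param name a clean binomial.
#' @param operator one of \code{concat_underscore}, \code{concat_zero},
#'   \code{concat_x}, \code{truncate_10}, \code{drop_leading_char},
#'   \code{strip_genus}, \code{author_noise}, \code{chresonym_swap},
#'   \code{misspell_ed_k}, \code{case_mangle}, \code{add_strain_tail},
#'   \code{add_acronym_tail}.
#' @param k number of edits for \code{misspell_ed_k}.
#' @param rng_state ignored by the deterministic operators; the stochastic
#'   ones (\code{misspell_ed_k}, \code{case_mangle}, tails, author noise)
#'   draw from the current RNG, so wrap calls in a seeded context (as
#'   [gn_simulate()] does) for reproducibility.
#' @return the corrupted string.
#' @export
corrupt_name <- function(name, operator, k = 1L, rng_state = NULL) {
  operator <- match.arg(operator, corruption_operators)
  switch(
    operator,
    concat_underscore = gsub(" ", "_", name, fixed = TRUE),
    concat_zero = gsub(" ", "0", name, fixed = TRUE),
    concat_x = gsub(" ", "X", name, fixed = TRUE),
    truncate_10 = substr(name, 1L, 10L),
    drop_leading_char = substring(name, 2L),
    strip_genus = sub("^\\S+\\s+", "", name),
    author_noise = paste(name, sample(author_pool, 1L)),
    chresonym_swap = paste(
      sub("\\s+[A-Z(].*$", "", name), sample(author_pool, 1L)
    ),
    misspell_ed_k = misspell(name, k),
    case_mangle = if (stats::runif(1) < 0.5) {
      toupper(name)
    } else {
      paste0(tolower(substr(name, 1, 1)), substring(name, 2))
    },
    add_strain_tail = paste0(
      name, " str. ", paste0(sample(LETTERS, 2L), collapse = ""),
      sample(10:99, 1L)
    ),
    add_acronym_tail = paste(
      name, sample(c("ATCC", "CBS", "NBRC", "JCM"), 1L),
      sample(1000:9999, 1L)
    )
  )
}

# introduce exactly k OSA edits into the letters of a name; verified
# against dl_distance and re-drawn on the rare occasions edits cancel
misspell <- function(name, k = 1L) {
  key0 <- match_key(name)
  for (attempt in 1:50) {
    out <- name
    for (e in seq_len(k)) {
      letters_at <- which(strsplit(out, "")[[1]] %in% letters)
      # leave the first character of each token intact when possible, so
      # single edits stay within what index banding can recover
      ok <- setdiff(letters_at, c(1L))
      pos <- if (length(ok)) sample(ok, 1L) else sample(letters_at, 1L)
      ch <- strsplit(out, "")[[1]]
      op <- sample(c("sub", "del", "ins", "swap"), 1L)
      out <- switch(
        op,
        sub = {
          ch[pos] <- sample(setdiff(letters, ch[pos]), 1L)
          paste(ch, collapse = "")
        },
        del = paste(ch[-pos], collapse = ""),
        ins = paste(
          c(ch[seq_len(pos)], sample(letters, 1L),
            ch[-seq_len(pos)]), collapse = ""
        ),
        swap = {
          if (pos < length(ch) && ch[pos + 1L] %in% letters &&
              ch[pos] != ch[pos + 1L]) {
            tmp <- ch[pos]; ch[pos] <- ch[pos + 1L]; ch[pos + 1L] <- tmp
          } else {
            ch[pos] <- sample(setdiff(letters, ch[pos]), 1L)
          }
          paste(ch, collapse = "")
        }
      )
    }
    if (!is.na(key0) &&
        dl_distance(key0, match_key(out)) == as.integer(k)) {
      return(out)
    }
  }
  stop("could not construct a distance-", k, " misspelling of '", name, "'")
}

#' Generate a synthetic dirty checklist with ground truth
#'
#' Draws one corruption operator (or none) per clean name according to the
#' supplied probability mix, applies it, and records the operator chain so
#' every dirty string carries its pristine ground truth. Reproducible under
#' the seed: identical inputs and seed give an identical output list.
#'
#' @param clean_names character vector of clean names (default the bundled
#'   [clean_binomials()]); must be nonempty.
#' @param mix named numeric vector of operator probabilities (names from
#'   the operator set, see [corrupt_name()]); probabilities must sum to at
#'   most 1 — the remainder is the probability of leaving a name clean.
#'   Operators may also be given as \code{"misspell_ed_2"} etc. to set
#'   \code{k}.
#' @param seed integer seed.
#' @return a tibble with columns \code{clean_name}, \code{dirty_name},
#'   \code{operators} (list of character vectors) and \code{seed}.
#' @examples
#' gn_simulate(c("Bison bison", "Danio rerio"),
#'             mix = c(concat_underscore = 1), seed = 1)
#' @export
gn_simulate <- function(clean_names = clean_binomials(),
                        mix = c(concat_underscore = 0.2, concat_zero = 0.1,
                                misspell_ed_1 = 0.2, case_mangle = 0.1,
                                author_noise = 0.1, add_strain_tail = 0.1),
                        seed = 42L) {
  if (!length(clean_names)) stop("'clean_names' must be nonempty")
  if (sum(mix) > 1 + 1e-9) stop("operator probabilities must sum to <= 1")
  base_ops <- sub("_ed_[0-9]+$", "_ed_k", names(mix))
  bad <- !base_ops %in% c(corruption_operators, "none")
  if (any(bad)) stop("unknown operator(s): ", paste(names(mix)[bad],
                                                    collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))

  choices <- c(names(mix), "none")
  probs <- c(unname(mix), 1 - sum(mix))
  picked <- sample(choices, length(clean_names), replace = TRUE,
                   prob = probs)
  dirty <- character(length(clean_names))
  ops <- vector("list", length(clean_names))
  for (i in seq_along(clean_names)) {
    if (picked[i] == "none") {
      dirty[i] <- clean_names[i]
      ops[[i]] <- character()
    } else {
      k <- 1L
      op <- picked[i]
      km <- stringi::stri_match_first_regex(op, "_ed_([0-9]+)$")[, 2]
      if (!is.na(km)) {
        k <- as.integer(km)
        op <- "misspell_ed_k"
      }
      dirty[i] <- corrupt_name(clean_names[i], op, k = k)
      ops[[i]] <- picked[i]
    }
  }
  tibble::tibble(
    clean_name = clean_names, dirty_name = dirty,
    operators = ops, seed = as.integer(seed)
  )
}
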