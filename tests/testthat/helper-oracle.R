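# Independent brute-force oracle for the restricted Damerau-Levenshtein
# (optimal string alignment) distance: plain recursion with memoisation,
# no shared code with the package implementation.
osa_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ca <- substr(a, i, i)
    cb <- substr(b, j, j)
    cost <- if (ca == cb) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + cost)
    if (i > 1L && j > 1L &&
        substr(a, i, i) == substr(b, j - 1L, j - 1L) &&
        substr(a, i - 1L, i - 1L) == substr(b, j, j)) {
      v <- min(v, rec(i - 2L, j - 2L) + 1L)
    }
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

random_string <- function(maxlen = 7L, alphabet = letters[1:5]) {
  n <- sample(0:maxlen, 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small paired checklists used by the cross-mapping tests
fixture_source <- function() {
  tibble::tibble(
    id = as.character(1:8),
    name = c(
      "Pseudomonas syringae",
      "Acer cappadocicum subsp. sinicum (Rehder) Hand.-Mazz.",
      "Cnemidophorus tigris aethiops",
      "Lysandra coridon gennargenti",
      "Dorsophila melanogaster",
      "Anolis barkeri (Schmidt, 1939)",
      "Papaver somnifera",
      "Nonexistent nothing"
    )
  )
}

fixture_target <- function() {
  tibble::tibble(
    id = paste0("t", 1:7),
    name = c(
      "Pseudomonas syringae",
      "Acer cappadocicum var. sinicum Rehd.",
      "Cnemidophorus tigris Baird & Girard, 1852",
      "Lysandra",
      "Drosophila melanogaster Meigen, 1830",
      "Anolis barkeri Schmidt, 1939",
      "Papaver somniferum L."
    )
  )
}

golden_classification <- function() {
  path <- system.file("extdata", "golden_classification.tsv",
                      package = "gnkit")
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    na.strings = NULL)
}

anolis_variants <- c(
  "Anolis barkeri",
  "Anolis barkeri (Schmidt, 1939)",
  "Anolis barkeri POWELL & BIRT 2001",
  "Anolis barkeri POWELL 2001",
  "Anolis barkeri Schmidt",
  "Anolis barkeri Schmidt 1939",
  "Anolis barkeri Schmidt, 1939"
)

paludibacter_variants <- c(
  "Paludibacter propionicigenes",
  "Paludibacter propionicigenes Ueki et al. 2006",
  "Paludibacter propionicigenes CCUG 53888",
  "Paludibacter propionicigenes JCM 13257",
  "Paludibacter propionicigenes str. WB4",
  "Paludibacter propionicigenes WB4",
  "Paludibacter propionicigenes DSM 17365"
)
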