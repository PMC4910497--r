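#' Load the term vocabularies
#'
#' Reads the YAML vocabulary file that drives rank-marker recognition in the
#' parser and term matching in the classifier. The packaged default is used
#' when \code{path} is \code{NULL}; sources with their own conventions can
#' supply an edited copy.
#'
#' @param path path to a vocabulary YAML file, or \code{NULL} for the
#'   packaged default.
#' @return a named list with components \code{rank_markers},
#'   \code{greek_rank_letters}, \code{single_letter_ranks},
#'   \code{annotations}, \code{annotation_patterns} and \code{classifier}.
#' @export
gn_vocab <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabulary.yaml", package = "gnkit")
  }
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  v <- yaml::read_yaml(path)
  needed <- c("rank_markers", "annotations", "classifier")
  missing <- setdiff(needed, names(v))
  if (length(missing)) {
    stop("vocabulary file lacks sections: ", paste(missing, collapse = ", "))
  }
  v
}

# cached default vocabulary (read once per session)
the <- new.env(parent = emptyenv())

default_vocab <- function() {
  if (is.null(the$vocab)) the$vocab <- gn_vocab()
  the$vocab
}
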