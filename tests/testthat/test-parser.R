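test_that("positional rank interpretation covers uninomial to trinomial", {
  p <- gn_parse(c("Bison", "Bison bison", "Bison bison bison",
                  "Bison bison athabascae", "Bos bison bison"))
  expect_equal(p$uninomial[1], "Bison")
  expect_true(all(is.na(p$genus[1])))
  expect_equal(p$genus[2:5], c("Bison", "Bison", "Bison", "Bos"))
  expect_equal(p$specific_epithet[2:5], rep("bison", 4))
  expect_equal(p$infraspecific[[4]]$epithet, "athabascae")
  expect_true(all(p$quality == "clean"))
})

test_that("rank markers attach to the following epithet, authorship captured", {
  p <- gn_parse("Carex scirpoidea Michx. ssp. convoluta (Kük.) Dunlop")
  expect_equal(p$genus, "Carex")
  expect_equal(p$specific_epithet, "scirpoidea")
  expect_equal(p$infraspecific[[1]]$rank_marker, "ssp.")
  expect_equal(p$infraspecific[[1]]$epithet, "convoluta")
  a <- p$authorship[[1]]
  expect_equal(a$combination_authors, "Dunlop")
  expect_equal(a$basionym_authors, "Kük.")
  expect_equal(p$quality, "clean")
})

test_that("empty and garbage inputs degrade to unparseable, never error", {
  p <- gn_parse(c("", "   ", "!!??", "123 456", "%$#@"))
  expect_true(all(p$quality == "unparseable"))
  expect_true(all(is.na(p$uninomial) & is.na(p$genus)))
})

test_that("unrecognized trailing tokens land in the tail", {
  p <- gn_parse("Characiformes sp. BOLD:AAC1024")
  expect_equal(p$uninomial, "Characiformes")
  expect_equal(p$annotations[[1]]$kind, "sp_indet")
  expect_equal(p$tail, "BOLD:AAC1024")
  expect_equal(p$quality, "with_tail")
})

test_that("hybrid signs are recognized in their encoding variants", {
  h <- detect_hybrid(c(
    "Magnolia heptapeta x Magnolia quinquepeta",
    "Magnolia heptapeta × Magnolia quinquepeta",
    "Magnolia heptapeta х Magnolia quinquepeta",
    "x Cuprocyparis leylandii",
    "Bison bison"
  ))
  expect_equal(h$hybrid_flag, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(h$components[[1]],
               c("Magnolia heptapeta", "Magnolia quinquepeta"))
  expect_equal(h$components[[4]], "Cuprocyparis leylandii")
  expect_length(h$components[[5]], 0)
})

test_that("lower-case genus is recovered and flagged", {
  p <- gn_parse("litoria ewingii")
  expect_equal(p$genus, "Litoria")
  expect_true(p$case_repaired)
  expect_equal(p$quality, "clean")
})

test_that("bracketed genus and bracketed year conventions are handled", {
  p <- gn_parse("[Bacillus] sp. KITNT-3")
  expect_equal(p$uninomial, "Bacillus")
  expect_true("nom_status" %in% p$annotations[[1]]$kind)
  p2 <- gn_parse("Athyma opalina (Kollar, [1844])")
  a <- p2$authorship[[1]]
  expect_equal(a$basionym_year, 1844L)
  expect_true(a$bracketed_year)
})

test_that("all-caps author styles parse but collection codes do not", {
  p <- gn_parse(c("Anolis barkeri POWELL & BIRT 2001",
                  "Paludibacter propionicigenes CCUG 53888"))
  expect_equal(p$authorship[[1]]$combination_authors, c("POWELL", "BIRT"))
  expect_equal(p$quality[1], "clean")
  expect_null(p$authorship[[2]])
  expect_equal(p$tail[2], "CCUG 53888")
})

test_that("parsing is total and deterministic over a broad corpus", {
  corpus <- c(golden_classification()$name, clean_binomials(),
              anolis_variants, paludibacter_variants)
  p1 <- gn_parse(corpus)
  p2 <- gn_parse(corpus)
  expect_identical(p1, p2)
  expect_true(all(p1$quality %in% c("clean", "with_tail", "unparseable")))
  # exactly one of uninomial / genus / unparseable
  one_of <- (!is.na(p1$uninomial)) + (!is.na(p1$genus)) +
    (p1$quality == "unparseable")
  expect_true(all(one_of == 1L))
  # infraspecific parts imply a specific epithet; clean implies empty tail
  has_infra <- vapply(p1$infraspecific, nrow, integer(1)) > 0L
  expect_true(all(!has_infra | !is.na(p1$specific_epithet)))
  expect_true(all(p1$quality != "clean" | p1$tail == ""))
})

test_that("every non-whitespace token is conserved across components", {
  names <- c(
    "Anolis barkeri Schmidt, 1939",
    "Carex scirpoidea Michx. ssp. convoluta (Kük.) Dunlop",
    "Characiformes sp. BOLD:AAC1024",
    "Paludibacter propionicigenes str. WB4",
    "Gambierodiscus aff toxicus",
    "Lutzomyia (Helcocyrtomyia) hartmanni",
    "Acanthurus cf. leucosternon LvH-2007",
    "Myxococcus Thaxter 1892 emend. Lang and Stackebrandt 2009"
  )
  p <- gn_parse(names)
  for (k in seq_along(names)) {
    got <- c(
      p$uninomial[k], p$genus[k],
      if (!is.na(p$subgenus[k])) paste0("(", p$subgenus[k], ")"),
      p$specific_epithet[k],
      p$infraspecific[[k]]$rank_marker, p$infraspecific[[k]]$epithet,
      p$annotations[[k]]$token,
      if (!is.null(p$authorship[[k]])) {
        strsplit(p$authorship[[k]]$verbatim, " ", fixed = TRUE)[[1]]
      },
      strsplit(p$tail[k], " ", fixed = TRUE)[[1]]
    )
    got <- got[!is.na(got) & nzchar(got)]
    want <- strsplit(p$normalized[k], " ", fixed = TRUE)[[1]]
    expect_setequal(got, want)
  }
})
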