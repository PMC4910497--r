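test_that("interpolated separators between genus and species become spaces", {
  r <- gn_preprocess(c("Triticum_aestivum", "Danio0reri", "DanioXreri",
                       "LissXtimor", "GallusXgal"))
  expect_equal(r$repaired[1], "Triticum aestivum")
  expect_equal(r$repaired[2], "Danio reri")
  expect_equal(r$repaired[3], "Danio reri")
  expect_true(all(vapply(r$flags, function(f) "deconcatenated" %in% f,
                         logical(1))))
})

test_that("ten-character repaired strings are flagged as truncation suspects", {
  r <- gn_preprocess(c("Danio0reri", "Bombyx0mor", "Triticum_aestivum"))
  expect_true("truncated_suspect" %in% r$flags[[1]])
  expect_true("truncated_suspect" %in% r$flags[[2]])
  expect_false("truncated_suspect" %in% r$flags[[3]])
  # truncations are not dictionary-expanded
  expect_equal(r$repaired[1], "Danio reri")
})

test_that("unsplittable strings are marked unresolvable, clean input untouched", {
  r <- gn_preprocess(c("corbulasulcata", "Bison bison", "Pan__Herm"))
  expect_true(r$unresolvable[1])
  expect_equal(r$repaired[1], "corbulasulcata")
  expect_false(r$unresolvable[2])
  expect_equal(r$repaired[2], "Bison bison")
  expect_length(r$flags[[2]], 0)
  # doubled separators are ambiguous, not a simple concatenation
  expect_true(r$unresolvable[3])
})

test_that("case damage is repaired and flagged", {
  r <- gn_preprocess(c("ARABIDOPSIS THALIANA", "litoria ewingii",
                       "Staphlococcus Aureus", "SECALE_CEREALE"))
  expect_equal(r$repaired,
               c("Arabidopsis thaliana", "Litoria ewingii",
                 "Staphlococcus aureus", "Secale cereale"))
  expect_true(all(vapply(r$flags, function(f) "case_repaired" %in% f,
                         logical(1))))
})

test_that("trailing accession tokens and separators are stripped", {
  r <- gn_preprocess(c("Didemnum_sp_AB211073.1", "Botryllus_planus_DQ346653",
                       "Hypericum patulum_"))
  expect_equal(r$repaired[1], "Didemnum sp")
  expect_equal(r$repaired[2], "Botryllus planus")
  expect_equal(r$repaired[3], "Hypericum patulum")
  expect_true(all(vapply(r$flags, function(f) "tail_stripped" %in% f,
                         logical(1))))
})

test_that("repair never invents letters and flags fire iff the string changed", {
  inputs <- c("Triticum_aestivum", "Danio0reri", "LissXtimor", "Bison bison",
              "corbulasulcata", "ARABIDOPSIS THALIANA", "Hypericum patulum_",
              clean_binomials()[1:30])
  r <- gn_preprocess(inputs)
  for (k in seq_along(inputs)) {
    # letters of the repaired string are a subsequence of the original's
    # (case-insensitively; separators map to spaces, tails may be dropped)
    orig_letters <- tolower(gsub("[^A-Za-z]", "", r$original[k]))
    rep_letters <- tolower(gsub("[^A-Za-z]", "", r$repaired[k]))
    pattern <- paste0(strsplit(rep_letters, "")[[1]], collapse = ".*")
    expect_true(grepl(pattern, orig_letters))
    expect_lte(nchar(rep_letters), nchar(orig_letters))
    # flags empty iff unchanged and resolvable
    expect_identical(
      length(r$flags[[k]]) == 0L,
      r$repaired[k] == r$original[k] && !r$unresolvable[k] ||
        r$unresolvable[k]
    )
  }
  # determinism
  expect_identical(gn_preprocess(inputs), r)
})

test_that("rules come from config and an empty rule set is rejected", {
  rules <- gn_rules()
  expect_true(all(vapply(rules, function(r) !is.null(r$id), logical(1))))
  expect_error(gn_preprocess("x", rules = list()), "nonempty")
})
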