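test_that("corruption operators reproduce the documented pathologies", {
  expect_equal(corrupt_name("Triticum aestivum", "concat_underscore"),
               "Triticum_aestivum")
  expect_equal(
    corrupt_name(corrupt_name("Bombyx mori", "concat_zero"), "truncate_10"),
    "Bombyx0mor"
  )
  expect_equal(corrupt_name("Danio rerio", "concat_x"), "DanioXrerio")
  expect_equal(corrupt_name("Ichneumon dorsalis", "drop_leading_char"),
               "chneumon dorsalis")
  expect_equal(corrupt_name("Stauroneis legumen", "strip_genus"), "legumen")
})

test_that("misspell_ed_k introduces exactly k edits, verified by dl_distance", {
  set.seed(11)
  names <- clean_binomials()[1:25]
  for (k in 1:2) {
    for (nm in names) {
      dirty <- corrupt_name(nm, "misspell_ed_k", k = k)
      expect_equal(dl_distance(match_key(nm), match_key(dirty)),
                   as.integer(k))
    }
  }
})

test_that("generation is reproducible under the seed and records operators", {
  cn <- clean_binomials()[1:40]
  a <- gn_simulate(cn, seed = 99)
  b <- gn_simulate(cn, seed = 99)
  expect_identical(a, b)
  c2 <- gn_simulate(cn, seed = 100)
  expect_false(identical(a$dirty_name, c2$dirty_name))
  untouched <- lengths(a$operators) == 0L
  expect_identical(a$dirty_name[untouched], a$clean_name[untouched])
  expect_error(gn_simulate(character()), "nonempty")
  expect_error(gn_simulate(cn, mix = c(concat_zero = 0.7, case_mangle = 0.7)),
               "sum")
})

test_that("preprocessing plus canonical matching recovers all concatenation and case corruptions", {
  cn <- clean_binomials()
  sim <- gn_simulate(
    cn,
    mix = c(concat_underscore = 0.3, concat_zero = 0.25, concat_x = 0.25,
            case_mangle = 0.2),
    seed = 2718
  )
  rep <- gn_preprocess(sim$dirty_name)
  got <- match_key(gn_canonical(rep$repaired, on_unparseable = "na")$standard)
  want <- match_key(gn_canonical(sim$clean_name)$standard)
  expect_identical(got, want)
})

test_that("fuzzy matching at tolerance 1 recovers all well-separated single misspellings", {
  cn <- clean_binomials()[seq(1, 200, by = 3)]
  keys <- match_key(cn)
  # names whose nearest other clean name is at least 3 edits away
  nearest <- vapply(seq_along(keys), function(i) {
    min(dl_distance(keys[i], keys[-i], max_tolerance = 3))
  }, integer(1))
  isolated <- which(nearest >= 3L)
  expect_gt(length(isolated), 20L)
  set.seed(31)
  dirty <- vapply(cn[isolated], corrupt_name, character(1),
                  operator = "misspell_ed_k", k = 1L)
  r <- gn_crossmap(
    tibble::tibble(id = as.character(isolated), name = unname(dirty)),
    tibble::tibble(id = as.character(seq_along(cn)), name = cn),
    match_params(1)
  )
  expect_true(all(r$category %in% c("canonical_exact", "canonical_fuzzy")))
  recovered <- vapply(seq_len(nrow(r)), function(k) {
    cn[isolated[k]] %in% r$targets[[k]]$target_name
  }, logical(1))
  expect_true(all(recovered))
})
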