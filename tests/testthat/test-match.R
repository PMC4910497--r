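test_that("dl_distance agrees with a brute-force oracle on random pairs", {
  set.seed(2024)
  for (k in 1:500) {
    a <- random_string()
    b <- random_string()
    expect_identical(dl_distance(a, b), osa_oracle(a, b))
  }
})

test_that("dl_distance is symmetric, zero iff equal, counts transpositions", {
  set.seed(7)
  for (k in 1:50) {
    a <- random_string()
    b <- random_string()
    expect_identical(dl_distance(a, b), dl_distance(b, a))
    expect_identical(dl_distance(a, a), 0L)
    expect_identical(dl_distance(a, b) == 0L, a == b)
  }
  expect_equal(dl_distance("dorsophila melanogaster",
                           "drosophila melanogaster"), 1L)
  expect_equal(dl_distance("ca", "ac"), 1L)
  expect_equal(dl_distance("ca", "ac", allow_transposition = FALSE), 2L)
})

test_that("the published six-difference fuzzy pair is reproduced", {
  src <- gn_canonical("Lasidioplodia pseudobromae")
  tgt <- gn_canonical(
    "Lasiodiplodia pseudotheobromae A.J.L. Phillips, A. Alves & Crous 2008"
  )
  expect_equal(dl_distance(src$match_key, tgt$match_key), 6L)
})

test_that("all equal-distance candidates are returned, sorted", {
  targets <- c("cumia", "mimia", "mucia", "mukia", "numia", "rumia", "bison")
  hits <- fuzzy_candidates("mumia", targets, match_params(1))
  expect_equal(nrow(hits), 6L)
  expect_true(all(hits$distance == 1L))
  expect_equal(hits$key, sort(hits$key))
  # tolerance 0: only exact-key hits
  expect_equal(nrow(fuzzy_candidates("mumia", targets, match_params(0))), 0L)
  expect_equal(
    fuzzy_candidates("mumia", c(targets, "mumia"), match_params(0))$key,
    "mumia"
  )
})

test_that("names missing their leading character are still recovered", {
  hits <- fuzzy_candidates(
    match_key(gn_canonical("chneumon dorsalis")$standard),
    match_key("Ichneumon dorsalis"),
    match_params(1)
  )
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 1L)
})

test_that("cross-mapping assigns the documented tiers", {
  r <- gn_crossmap(fixture_source(), fixture_target(), match_params(2))
  by_name <- stats::setNames(r$category, r$source_name)
  expect_equal(unname(by_name["Pseudomonas syringae"]), "exact")
  expect_equal(
    unname(by_name["Acer cappadocicum subsp. sinicum (Rehder) Hand.-Mazz."]),
    "canonical_exact"
  )
  expect_equal(unname(by_name["Cnemidophorus tigris aethiops"]),
               "partial_canonical")
  expect_equal(unname(by_name["Lysandra coridon gennargenti"]), "genus_part")
  expect_equal(unname(by_name["Dorsophila melanogaster"]), "canonical_fuzzy")
  expect_equal(r$edit_distance[r$source_name == "Dorsophila melanogaster"], 1L)
  expect_equal(unname(by_name["Nonexistent nothing"]), "none")
})

test_that("a record with an exact hit is never reported under another tier", {
  src <- fixture_source()
  tgt <- fixture_target()
  r <- gn_crossmap(src, tgt, match_params(6))
  exact_names <- intersect(src$name, tgt$name)
  expect_true(all(r$category[r$source_name %in% exact_names] == "exact"))
  expect_true(all(r$category[!r$source_name %in% exact_names] != "exact"))
})

test_that("raising the tolerance never removes or re-categorizes earlier matches", {
  src <- fixture_source()
  tgt <- fixture_target()
  prev <- gn_crossmap(src, tgt, match_params(1))
  for (tol in 2:4) {
    cur <- gn_crossmap(src, tgt, match_params(tol))
    was_matched <- prev$category != "none"
    expect_true(all(cur$category[was_matched] == prev$category[was_matched]))
    expect_true(all(cur$n_targets[was_matched] >= prev$n_targets[was_matched]))
    prev <- cur
  }
})

test_that("multi-target inflation is exposed in the profile", {
  src <- tibble::tibble(id = "1", name = "Bothrops taeniata")
  tgt <- tibble::tibble(
    id = c("a", "b"),
    name = c("Bothrops taeniatus Wagler, 1824",
             "Bothrops taeniatus Kornacker, 1999")
  )
  r <- gn_crossmap(src, tgt, match_params(1))
  expect_equal(r$n_targets, 2L)
  p <- crossmap_profile(r)
  expect_equal(p$inflation, 1)
  expect_equal(sum(p$categories$n), 1L)
})

test_that("duplicate source ids error and an empty target yields all none", {
  src <- tibble::tibble(id = c("1", "1"), name = c("A b", "C d"))
  expect_error(gn_crossmap(src, fixture_target()), "duplicate")
  r <- gn_crossmap(fixture_source(),
                   tibble::tibble(id = character(), name = character()))
  expect_true(all(r$category == "none"))
})

test_that("homonym alerts fire on the configured list", {
  src <- tibble::tibble(id = "1", name = "Pieris japonica")
  tgt <- tibble::tibble(id = "a", name = "Pieris japonica Shirozu, 1952")
  r <- gn_crossmap(src, tgt)
  expect_true(r$homonym_alert)
  r2 <- gn_crossmap(src, tgt, homonyms = character())
  expect_false(r2$homonym_alert)
})

test_that("human-check flag is equivalent to confidence at or below 0.5", {
  r <- gn_crossmap(fixture_source(), fixture_target(), match_params(6))
  matched <- r[r$category != "none", ]
  expect_identical(matched$needs_human_check, matched$confidence <= 0.5)
})
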