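# Contact types, interaction modes and family classes.

test_that("exactly nine contact types exist in canonical order", {
  ct <- contact_types()
  expect_length(ct, 9)
  expect_equal(ct, c("H-Bb", "H-Mj", "H-Mn", "S-Bb", "S-Mj", "S-Mn",
                     "L-Bb", "L-Mj", "L-Mn"))
})

test_that("contact typing maps element pairs and discards unclassified", {
  expect_equal(contact_type("Helix", "MajorGroove"), "H-Mj")
  expect_equal(contact_type("Loop", "Backbone"), "L-Bb")
  expect_true(is.na(contact_type("Loop", "Unclassified")))
})

test_that("modes collapse duplicates and render in canonical order", {
  cts <- data.frame(protein_element = rep("Helix", 5),
                    dna_element = rep("Backbone", 5))
  m <- interaction_mode(cts)
  expect_equal(m$types, "H-Bb")
  expect_equal(mode_label(c("L-Mn", "H-Bb")), "(H-Bb) (L-Mn)")
  expect_equal(mode_label(c("L-Mn", "H-Bb"), display = TRUE),
               "(H - Bb) (L - Mn)")
  empty <- interaction_mode(data.frame(protein_element = character(0),
                                       dna_element = character(0)))
  expect_true(empty$non_interacting)
})

test_that("the number of possible modes is the subset count", {
  expect_identical(enumerate_possible_modes(), 511L)
  expect_identical(enumerate_possible_modes(1), 1L)
  # exhaustive enumeration oracle: all distinct non-empty subsets of the
  # nine labels
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 9)))
  labels <- apply(grid, 1, function(m) paste(contact_types()[m], collapse = "+"))
  expect_identical(enumerate_possible_modes(),
                   length(unique(labels[labels != ""])))
})

test_that("domain unions and family classes follow the set algebra", {
  expect_equal(domain_union(list(c("H-Bb"), c("H-Bb", "H-Mj"))),
               c("H-Bb", "H-Mj"))
  expect_equal(domain_union(list(c("S-Mj"))), "S-Mj")

  cl <- family_interaction_class(
    list(d1 = c("H-Bb", "H-Mj"), d2 = c("H-Bb", "L-Bb"), d3 = "H-Bb"), "f")
  expect_equal(cl$characteristic_types, "H-Bb")
  expect_false(cl$miscellaneous)

  cl2 <- family_interaction_class(
    list(d1 = "H-Bb", d2 = "S-Bb", d3 = "L-Bb"), "f")
  expect_true(cl2$miscellaneous)
  expect_length(cl2$characteristic_types, 0)

  expect_error(family_interaction_class(list(d1 = "H-Bb", d2 = "H-Bb"), "f"),
               "too few domains")
})

test_that("set-algebra results match a brute-force subset oracle", {
  all9 <- contact_types()
  set.seed(7)
  for (rep_ in 1:20) {
    ndom <- sample(3:6, 1)
    unions <- lapply(seq_len(ndom), function(i)
      sort(sample(all9, sample(1:5, 1))))
    names(unions) <- paste0("d", seq_len(ndom))
    cl <- family_interaction_class(lapply(unions, sort_types), "f")
    # oracle: a type is characteristic iff present in every union
    want <- all9[vapply(all9, function(t)
      all(vapply(unions, function(u) t %in% u, logical(1))), logical(1))]
    expect_equal(cl$characteristic_types, want)
    expect_equal(cl$miscellaneous, length(want) == 0)
  }
})

test_that("unions grow and classes shrink monotonically", {
  all9 <- contact_types()
  set.seed(11)
  for (rep_ in 1:10) {
    u1 <- sort_types(sample(all9, 3))
    extra <- sort_types(sample(all9, 2))
    grown <- domain_union(list(u1, extra))
    expect_true(all(u1 %in% grown))
    # adding a domain can only shrink (or keep) the class
    base <- list(a = u1, b = grown, c = sort_types(sample(all9, 4)))
    cl1 <- family_interaction_class(base, "f")
    cl2 <- family_interaction_class(c(base, list(d = sort_types(sample(all9, 2)))), "f")
    expect_true(all(cl2$characteristic_types %in% cl1$characteristic_types))
  }
})

test_that("report tables count families and structures", {
  modes <- data.frame(
    structure_id = c("s1", "s2", "s3", "s4"),
    domain_id = c("d1", "d2", "d3", "d3"),
    family_id = c("f1", "f1", "f2", "f2"),
    mode = c("(H-Bb)", "(H-Bb)", "(H-Bb)", "(L-Mn)"))
  classes <- data.frame(family_id = c("f1", "f2"),
                        class = c("(H-Bb)", "(H-Bb)"),
                        miscellaneous = FALSE, n_domains = c(2L, 1L))
  tabs <- build_reports(modes, classes)
  row <- tabs$mode_table[tabs$mode_table$mode == "(H-Bb)", ]
  expect_equal(row$n_families, 2L)
  expect_equal(row$n_structures, 3L)
  expect_equal(nrow(tabs$class_table), 1)     # both families share one class
  expect_equal(tabs$class_table$n_families, 2L)

  emptyt <- build_reports(modes[0, ], classes[0, ])
  expect_equal(nrow(emptyt$mode_table), 0)
  expect_equal(nrow(emptyt$class_table), 0)
})

test_that("every reported mode is one of the 511 subsets", {
  all9 <- contact_types()
  fx <- fixture_one_probe("helix", "MajorGroove", "hbond")
  rep_ <- analyze_structure(fx$structure, fx$domain, all_rows = TRUE,
                            shape = FALSE)
  ty <- rep_$domains[[1]]$mode$types
  expect_true(length(ty) >= 1 && all(ty %in% all9))
})
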