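test_that("CSV field round-trips through the neighbor-list dialect", {
  f <- path_field(3, strain = c(0.1, 0.2, 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scaffold_csv(f, path)
  back <- read_scaffold_field(path)
  expect_equal(back$elements$element_id, 1:3)
  expect_equal(back$elements$max_principal_strain, c(0.1, 0.2, 0.3))
  expect_equal(back$edges, f$edges)
})

test_that("negative strains are clamped to zero with a warning", {
  df <- data.frame(element_id = 1:3, volume = 1,
                   max_principal_strain = c(0.1, -0.05, 0.2))
  expect_warning(f <- scaffold_field(df), "clamped")
  expect_equal(f$elements$max_principal_strain, c(0.1, 0, 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("element_id,volume,max_principal_strain,neighbors",
               "1,1,0.1,2", "2,1,-0.05,1;3", "3,1,0.2,2"), path)
  expect_warning(g <- read_scaffold_field(path), "1 negative")
  expect_equal(g$elements$max_principal_strain[2], 0)
})

test_that("malformed fields are rejected with located errors", {
  dup <- data.frame(element_id = c(1, 2, 2), volume = 1,
                    max_principal_strain = 0.1)
  expect_error(scaffold_field(dup), "duplicate.*3")
  badv <- data.frame(element_id = 1:2, volume = c(1, 0),
                     max_principal_strain = 0.1)
  expect_error(scaffold_field(badv), "volume at row")
  expect_error(scaffold_field(data.frame(element_id = 1, volume = 1)),
               "missing column")
  df <- data.frame(element_id = 1:2, volume = 1,
                   max_principal_strain = 0.1)
  expect_error(scaffold_field(df, edges = cbind(1, 3)), "unknown element")
  expect_error(scaffold_field(df, edges = cbind(1, 1)), "self-adjacency")
  expect_error(scaffold_field(df[0, ]), "at least one element")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("element_id,volume,max_principal_strain,neighbors",
               "1,1,0.1,", "1,1,0.2,"), path)
  expect_error(read_scaffold_field(path), "duplicate")
})

test_that("mass loss ratio is dead mass over total mass", {
  f10 <- scaffold_field(data.frame(element_id = 1:10, volume = 1,
                                   max_principal_strain = 0.1))
  expect_equal(mass_loss_ratio(kill_elements(f10, c(2, 5, 9)), f10), 0.30)
  expect_identical(mass_loss_ratio(scaffold_state(f10), f10), 0)
  f3 <- scaffold_field(data.frame(element_id = 1:3, volume = c(1, 2, 3),
                                  max_principal_strain = 0.1))
  expect_equal(mass_loss_ratio(kill_elements(f3, 3), f3), 0.5)
  expect_equal(mass_loss_ratio(kill_elements(f3, 1:3), f3), 1)
})

test_that("strain histogram bins mass with open end bins summing to 1", {
  one <- scaffold_field(data.frame(element_id = 1:4, volume = 1,
                                   max_principal_strain = 0.2))
  h <- strain_histogram(one, bin_edges = c(0.29, 0.16))
  expect_equal(h$mass_fraction, c(0, 1, 0))   # all in [0.16, 0.29)
  two <- scaffold_field(data.frame(element_id = 1:2, volume = 1,
                                   max_principal_strain = c(0.05, 0.2)))
  h2 <- strain_histogram(two)                 # default representative edges
  expect_equal(h2$mass_fraction[h2$lower == 0.047 & h2$upper == 0.067], 0.5)
  expect_equal(h2$mass_fraction[h2$lower == 0.16 & h2$upper == 0.29], 0.5)
  expect_equal(sum(h2$mass_fraction), 1, tolerance = 1e-12)
  # mass weighting: heavier element dominates its bin
  wt <- scaffold_field(data.frame(element_id = 1:2, volume = c(3, 1),
                                  max_principal_strain = c(0.05, 0.2)))
  hw <- strain_histogram(wt)
  expect_equal(hw$mass_fraction[hw$lower == 0.047 & hw$upper == 0.067], 0.75)
  expect_error(strain_histogram(two, bin_edges = c(0.1, 0.3, 0.2)),
               "monotone")
})

test_that("histogram fractions sum to 1 for random fields", {
  set.seed(5)
  for (i in 1:5) {
    f <- scaffold_field(data.frame(element_id = 1:50, volume = runif(50),
                                   max_principal_strain = runif(50, 0, 0.6)))
    expect_equal(sum(strain_histogram(f)$mass_fraction), 1,
                 tolerance = 1e-12)
  }
})

test_that("discontinuity detection counts alive components", {
  p5 <- path_field(5)
  expect_equal(detect_discontinuity(p5)$n_components, 1L)
  broken <- detect_discontinuity(p5, kill_elements(p5, 3))
  expect_equal(broken$n_components, 2L)
  expect_true(broken$fragmented)
  expect_setequal(unlist(broken$components), c(1, 2, 4, 5))

  r8 <- ring_field(8)
  expect_false(detect_discontinuity(r8, kill_elements(r8, 1))$fragmented)
  two_dead <- detect_discontinuity(r8, kill_elements(r8, c(1, 5)))
  expect_equal(two_dead$n_components, 2L)
})

test_that("component counts match a union-find enumeration oracle", {
  union_find_components <- function(ids, edges, alive) {
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    live <- ids[alive]
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      if (a %in% live && b %in% live) {
        ra <- find(match(a, ids)); rb <- find(match(b, ids))
        if (ra != rb) parent[rb] <- ra
      }
    }
    length(unique(vapply(which(alive), find, 1L)))
  }
  f <- generate_stent_field(stent_field_spec(n_rings = 2, seed = 9))
  set.seed(21)
  for (i in 1:5) {
    alive <- runif(nrow(f$elements)) > 0.3
    if (!any(alive)) next
    st <- scaffold_state(f)
    st$alive <- alive
    expect_equal(detect_discontinuity(f, st)$n_components,
                 union_find_components(f$elements$element_id, f$edges,
                                       alive))
  }
})

test_that("state and field consistency is enforced", {
  f <- path_field(4)
  st <- scaffold_state(path_field(5))
  expect_error(mass_loss_ratio(st, f), "different numbers")
  expect_error(capacity_surrogate(st, f), "different numbers")
})
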