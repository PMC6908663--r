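trees_I <- build_trees(fig2_fixture("I"))

test_that("ancestral chains walk rootward", {
  expect_equal(ancestral_chain(trees_I$species, "Be"),
               c("Be", "Bb", "Aa", "ancestor"))
  expect_equal(ancestral_chain(trees_I$species, "ancestor"), "ancestor")
  expect_error(ancestral_chain(trees_I$species, "nope"), "unknown species")
  # deep random path: chain base ages strictly increase rootward
  tr <- build_trees(random_fixture(fixture_spec(seed = 11, n_species = 12,
                                                max_depth = 12)))
  for (sp in names(tr$species$ranges)) {
    ch <- ancestral_chain(tr$species, sp)
    bases <- vapply(ch, function(s) max(tr$species$ranges[[s]]$points$age),
                    numeric(1))
    expect_true(all(diff(bases) > 0))
    # agrees with a brute-force parent walk
    brute <- sp
    while (brute[length(brute)] %in% tr$species$branches$child) {
      b <- tr$species$branches
      brute <- c(brute, b$parent[b$child == brute[length(brute)]])
    }
    expect_equal(ch, brute)
  }
})

test_that("a phenon crossing one species origin breaks into two segments", {
  segs <- split_phenon(trees_I$phenon$ranges$b, trees_I$species)
  expect_length(segs, 2)
  # youngest first: the part in Bb, then the transfer into Aa
  expect_equal(segs[[1]]$species, "Bb")
  expect_equal(c(segs[[1]]$old_age, segs[[1]]$young_age), c(10, 8))
  expect_equal(segs[[1]]$top_symbol, "RANGE_TOP_EXTINCT")
  expect_equal(segs[[1]]$base_symbol, "BROKEN_BASE")
  expect_equal(segs[[2]]$species, "Aa")
  expect_equal(c(segs[[2]]$old_age, segs[[2]]$young_age), c(12, 10))
  expect_equal(segs[[2]]$top_symbol, "BROKEN_TOP")
  expect_equal(segs[[2]]$base_symbol, "RANGE_ORIGIN")
})

test_that("a phenon wholly inside its species stays in one piece", {
  segs <- split_phenon(trees_I$phenon$ranges$e, trees_I$species)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$species, "Be")
  expect_equal(segs[[1]]$top_symbol, "RANGE_TOP_LIVING")
  expect_equal(segs[[1]]$base_symbol, "RANGE_ORIGIN")
})

test_that("an origin coinciding with a speciation stays in that species", {
  # phenon a spans exactly Aa (13-0): no segment leaks into the ancestor
  segs <- split_phenon(trees_I$phenon$ranges$a, trees_I$species)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$species, "Aa")
  # style intervals are carried (conjectured 5-0, frequent 13-5)
  expect_equal(segs[[1]]$styles$style, c("frequent", "conjectured"))
})

test_that("segments re-cut the phenon's style intervals at break ages", {
  tr <- build_trees(mini_pack(
    c("A", "20", "frequent"), c("A", "0", "TOP"),
    c("B", "10", "frequent"), c("B", "0", "TOP"),
    c("A", "10", "branch", "B", "on"),
    c("P", "16", "rare"), c("P", "6", "conjectured"),
    c("P", "2", "TOP", "", "", "phenon", "B")))
  segs <- split_phenon(tr$phenon$ranges$P, tr$species)
  expect_length(segs, 2)
  # young piece (10-2) in B: rare 10-6 then conjectured 6-2
  expect_equal(segs[[1]]$styles$style, c("rare", "conjectured"))
  expect_equal(segs[[1]]$styles$old, c(10, 6))
  expect_equal(segs[[1]]$styles$young, c(6, 2))
  # old piece (16-10) in A: rare throughout
  expect_equal(segs[[2]]$styles$style, "rare")
  expect_equal(c(segs[[2]]$styles$old, segs[[2]]$styles$young), c(16, 10))
})

test_that("out-of-place phena raise the documented errors", {
  # TOP older than the terminal species' base
  tr <- build_trees(mini_pack(
    c("A", "6", "frequent"), c("A", "2", "TOP"),
    c("P", "9", "common"), c("P", "7", "TOP", "", "", "phenon", "A")))
  expect_error(split_phenon(tr$phenon$ranges$P, tr$species),
               "ends outside its species")
  # TOP younger than the terminal species' top (phenon outlives its host)
  trh <- build_trees(mini_pack(
    c("A", "10", "frequent"), c("A", "8", "TOP"),
    c("P", "9", "common"), c("P", "5", "TOP", "", "", "phenon", "A")))
  expect_error(split_phenon(trh$phenon$ranges$P, trh$species),
               "ends outside its species")
  # TOP exactly at the base age is the same error (the whole phenon
  # belongs to the ancestor, which must then be named instead)
  tr2 <- build_trees(mini_pack(
    c("A", "10", "frequent"), c("A", "0", "TOP"),
    c("B", "6", "frequent"), c("B", "2", "TOP"),
    c("A", "6", "branch", "B", "on"),
    c("P", "9", "common"), c("P", "6", "TOP", "", "", "phenon", "B")))
  expect_error(split_phenon(tr2$phenon$ranges$P, tr2$species),
               "ends outside its species")
  # BASE older than the chain root's origination
  tr3 <- build_trees(mini_pack(
    c("A", "10", "frequent"), c("A", "0", "TOP"),
    c("P", "12", "common"), c("P", "2", "TOP", "", "", "phenon", "A")))
  expect_error(split_phenon(tr3$phenon$ranges$P, tr3$species),
               "predates root species")
})

test_that("the relationship map reproduces the worked example's groups and ids", {
  map <- compute_relationship_map(trees_I$species, trees_I$phenon)
  expect_equal(map$species_order, c("ancestor", "Aa", "Bb", "Be", "Bf"))
  sizes <- vapply(map$groups, length, integer(1))
  expect_equal(unname(sizes[map$species_order]), c(1, 2, 4, 3, 1))
  member <- function(sp) vapply(map$groups[[sp]], `[[`, character(1), "phenon")
  expect_equal(member("ancestor"), "phenon")
  expect_equal(member("Aa"), c("a", "b"))
  expect_equal(member("Bb"), c("b", "c", "d", "f"))
  expect_equal(member("Be"), c("c", "d", "e"))
  expect_equal(member("Bf"), "f")
  # strictly sequential ids within each species group
  e <- map$entries
  expect_equal(e$id[e$species == "Bb"], c("3-1", "3-2", "3-3", "3-4"))
  expect_equal(e$id[e$species == "Be"], c("4-1", "4-2", "4-3"))
  expect_equal(e$id[e$species == "ancestor"], "1-1")
})

test_that("species with no phena get empty groups", {
  tr <- build_trees(mini_pack(
    c("A", "10", "frequent"), c("A", "0", "TOP"),
    c("B", "6", "frequent"), c("B", "0", "TOP"),
    c("A", "6", "branch", "B", "on"),
    c("P", "5", "common"), c("P", "1", "TOP", "", "", "phenon", "B")))
  map <- compute_relationship_map(tr$species, tr$phenon)
  expect_length(map$groups$A, 0)
  expect_length(map$groups$B, 1)
  expect_equal(map$entries$id, "2-1")
})

test_that("breaking up the phenon tree leaves disconnected subtrees in boxes", {
  map <- compute_relationship_map(trees_I$species, trees_I$phenon)
  be <- subtrees_in_box(map, trees_I$phenon, "Be")
  expect_length(be, 2)
  expect_equal(vapply(be[[1]], `[[`, character(1), "phenon"), "c")
  expect_equal(vapply(be[[2]], `[[`, character(1), "phenon"), c("d", "e"))
  # Bb hosts one connected subtree rooted at b
  bb <- subtrees_in_box(map, trees_I$phenon, "Bb")
  expect_length(bb, 1)
  expect_equal(vapply(bb[[1]], `[[`, character(1), "phenon"),
               c("b", "c", "d", "f"))
  # a box with a single unsplit phenon holds one singleton subtree
  anc <- subtrees_in_box(map, trees_I$phenon, "ancestor")
  expect_length(anc, 1)
  expect_length(anc[[1]], 1)
})

test_that("box subtree partition equals graph components on random fixtures", {
  for (seed in 1:30) {
    tr <- build_trees(random_fixture(fixture_spec(seed = seed,
                                                  crossing_prob = 0.5,
                                                  link_prob = 0.7)))
    map <- compute_relationship_map(tr$species, tr$phenon)
    for (sp in map$species_order) {
      got <- lapply(subtrees_in_box(map, tr$phenon, sp), function(s)
        sort(vapply(s, `[[`, character(1), "phenon")))
      want <- oracle_box_components(tr, map, sp)
      expect_setequal(got, want)
    }
  }
})

test_that("group ordering modes sort as documented and are stable", {
  segs <- list(fake_seg("f", 7, 1), fake_seg("c", 9, 3), fake_seg("d", 8, 0))
  first <- order_group(segs, "first")
  expect_equal(vapply(first, function(s) s[[1]]$phenon, character(1)),
               c("c", "d", "f"))
  last <- order_group(segs, "last")
  expect_equal(vapply(last, function(s) s[[1]]$phenon, character(1)),
               c("d", "f", "c"))
  alpha <- order_group(segs, "alphabetic")
  expect_equal(vapply(alpha, function(s) s[[1]]$phenon, character(1)),
               c("c", "d", "f"))
  # equal keys keep input order
  ties <- order_group(list(fake_seg("x", 5, 0), fake_seg("y", 5, 1)), "first")
  expect_equal(vapply(ties, function(s) s[[1]]$phenon, character(1)),
               c("x", "y"))
  # alphabetic uses the display label, not the raw name
  disp <- order_group(list(fake_seg("z | long", 5, 0), fake_seg("a", 4, 0)),
                      "alphabetic")
  expect_equal(disp[[2]][[1]]$label_display, "z")
})

test_that("split segments match the interval oracle and conserve the range", {
  for (seed in 1:200) {
    tr <- build_trees(random_fixture(fixture_spec(
      seed = seed, n_species = 5, n_phena = 8, crossing_prob = 0.6)))
    trees <- list(species = tr$species, phenon = tr$phenon)
    for (ph in names(tr$phenon$ranges)) {
      got <- observed_split(trees, ph)
      want <- oracle_split(trees, ph)
      expect_equal(got, want, tolerance = 1e-12)
      # conservation: union of segments is the original interval
      rng <- tr$phenon$ranges[[ph]]
      expect_equal(min(got$young), min(rng$points$age))
      expect_equal(max(got$old), max(rng$points$age))
      if (nrow(got) > 1) {
        # adjacent segments share their cut age exactly; no overlap
        expect_equal(got$old[-nrow(got)], got$young[-1])
      }
      # containment in host species
      for (i in seq_len(nrow(got))) {
        host <- tr$species$ranges[[got$species[i]]]
        expect_gte(got$young[i], min(host$points$age) - 1e-9)
        expect_lte(got$old[i], max(host$points$age) + 1e-9)
      }
    }
  }
})

test_that("guide symbols pair up across breaks", {
  for (seed in 1:50) {
    tr <- build_trees(random_fixture(fixture_spec(
      seed = seed, n_species = 5, n_phena = 8, crossing_prob = 0.7)))
    for (ph in names(tr$phenon$ranges)) {
      segs <- split_phenon(tr$phenon$ranges[[ph]], tr$species)
      tops <- vapply(segs, `[[`, character(1), "top_symbol")
      bases <- vapply(segs, `[[`, character(1), "base_symbol")
      expect_equal(sum(bases == "RANGE_ORIGIN"), 1)
      expect_equal(sum(tops %in% c("RANGE_TOP_EXTINCT", "RANGE_TOP_LIVING")), 1)
      expect_equal(sum(tops == "BROKEN_TOP"), sum(bases == "BROKEN_BASE"))
      n <- length(segs)
      if (n > 1) for (k in seq_len(n - 1)) {
        expect_equal(segs[[k]]$base_symbol, "BROKEN_BASE")
        expect_equal(segs[[k + 1]]$top_symbol, "BROKEN_TOP")
        # matched pair at the same age, in child/parent species
        expect_equal(segs[[k]]$old_age, segs[[k + 1]]$young_age)
      }
    }
  }
})

test_that("integration preserves the species tree untouched", {
  before <- build_trees(fig2_fixture("I"))$species
  map <- compute_relationship_map(trees_I$species, trees_I$phenon)
  expect_setequal(map$species_order, names(before$ranges))
  expect_identical(trees_I$species$branches, before$branches)
  for (sp in names(before$ranges))
    expect_identical(trees_I$species$ranges[[sp]]$points,
                     before$ranges[[sp]]$points)
})

test_that("the relationship table mirrors the map", {
  map <- compute_relationship_map(trees_I$species, trees_I$phenon)
  tab <- relationship_table(map)
  expect_named(tab, c("relationship_id", "species", "group_size", "phenon",
                      "relation"))
  expect_equal(nrow(tab), 11)
  expect_equal(tab$group_size[tab$species == "Bb"], rep(4, 4))
  expect_equal(tab$relation[tab$relationship_id == "1-1"],
               "ancestor ← phenon")
  p <- file.path(tempdir(), "map.tsv")
  relationship_table(map, path = p)
  back <- read.delim(p, fileEncoding = "UTF-8")
  expect_equal(nrow(back), 11)
  unlink(p)
})
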