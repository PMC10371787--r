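test_that("maximal_matches equals a brute-force antiparallel scan", {
  for (seed in 1:5) {
    set.seed(seed)
    sc_chars <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    sc <- scaffold(paste(sc_chars, collapse = ""), circular = seed %% 2 == 0)
    stc <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
    got <- maximal_matches(stc, sc, 4L)
    want <- oracle_matches(stc, sc_chars, 4L, sc$circular, "DNA")
    want <- if (length(want)) as.data.frame(do.call(rbind, want)) else
      data.frame(start = integer(0), mu = integer(0))
    expect_equal(got[order(got$start), ], want[order(want$start), ],
                 ignore_attr = TRUE)
  }
})

test_that("a staple with no complementarity gives no matches", {
  sc <- scaffold(strrep("A", 60))                # requires staple T
  expect_equal(nrow(maximal_matches(rep("A", 12), sc, 6L)), 0L)
})

test_that("greedy matching overshoots a designed junction into one maximal run", {
  # staple designed to split 16-16, but complementarity continues one base
  # past the crossover: the first match is mu = 17 and the only complete
  # tiling is 17-15
  set.seed(8)
  n <- 300L
  sc_chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  stc <- sample(c("A", "C", "G", "T"), 32, replace = TRUE)
  inv <- c(T = "A", A = "T", G = "C", C = "G")
  s1 <- 100L; s2 <- 220L
  # sections: staple 0..16 at s1 (17 complementary bases = designed 16 + 1
  # overshoot), staple 16..31 at s2 (16 bases)
  for (j in 0:16) sc_chars[s1 - j + 1L] <- inv[[stc[j + 1L]]]
  for (j in 0:15) sc_chars[s2 - j + 1L] <- inv[[stc[17L + j]]]
  # kill accidental extensions
  if (inv[[stc[18L]]] == sc_chars[s1 - 17L + 1L]) sc_chars[s1 - 17L + 1L] <-
      setdiff(c("A", "C", "G", "T"), inv[[stc[18L]]])[1]
  if (inv[[stc[32L]]] == sc_chars[s2 - 16L + 1L]) sc_chars[s2 - 16L + 1L] <-
      setdiff(c("A", "C", "G", "T"), inv[[stc[32L]]])[1]
  sc <- scaffold(paste(sc_chars, collapse = ""), circular = FALSE)

  mm <- maximal_matches(stc, sc, 6L)
  expect_true(any(mm$start == s1 & mm$mu == 17L))
  expect_false(any(mm$start == s1 & mm$mu == 16L))   # no sub-maximal split

  v <- list(vid = 0L, parent_id = 0L, parent_segment_index = 0L,
            offset = 0L, chars = stc, length = 32L)
  srt <- build_srt(v, sc, 6L, sigma = 32L)
  sigs <- route_signatures(srt)
  expect_true(sprintf("%d:17|%d:15", s1, s2 - 1L) %in% sigs)
  expect_false(any(grepl(sprintf("^%d:16", s1), sigs)))
})

test_that("build_srt with sigma >= staple length equals exhaustive enumeration", {
  for (seed in 1:6) {
    fd <- small_fixture(seed, rows = 2, cols = 40, section_len = 8)
    sc <- fd$design$scaffold
    vs <- split_virtual(fd$design)
    for (v in vs) {
      srt <- build_srt(v, sc, 6L, sigma = v$length)
      expect_equal(route_signatures(srt),
                   oracle_routes(v$chars, sc$chars, 6L, sc$circular,
                                 sc$material))
    }
  }
})

test_that("route sets are monotone in sigma and mu_min", {
  for (seed in c(3, 12)) {
    fd <- small_fixture(seed, rows = 2, cols = 48, section_len = 8,
                        hardened = FALSE)
    sc <- fd$design$scaffold
    vs <- split_virtual(fd$design)
    for (v in vs[c(1, 3, 5)]) {
      r_s0 <- route_signatures(build_srt(v, sc, 6L, 0L))
      r_s3 <- route_signatures(build_srt(v, sc, 6L, 3L))
      r_sL <- route_signatures(build_srt(v, sc, 6L, v$length))
      expect_true(all(r_s0 %in% r_s3))
      expect_true(all(r_s3 %in% r_sL))
      r_m8 <- route_signatures(build_srt(v, sc, 8L, v$length))
      expect_true(all(r_m8 %in% r_sL))    # raising mu_min never adds routes
    }
  }
})

test_that("unique-k-mer scaffolds give exactly one route per staple", {
  fd <- forward_design(4, 48, section_len = 8, scaffold_kind = "debruijn",
                       debruijn_k = 7, seed = 2)
  sc <- fd$design$scaffold
  vs <- split_virtual(fd$design)
  srts <- lapply(vs, build_srt, sc = sc, mu_min = 6L, sigma = 0L)
  nr <- vapply(srts, function(s) length(s$routes), integer(1))
  expect_true(all(nr == 1L))
  # single-route SRT: footprint is maximal (= the whole route)
  expect_equal(sort(footprint(srts[[1]])), sort(srts[[1]]$routes[[1]]$bases))
})

test_that("footprint is the intersection of route base sets", {
  # staple with two disjoint binding sites -> empty footprint
  set.seed(21)
  sc_chars <- sample(c("A", "C", "G", "T"), 240, replace = TRUE)
  stc <- sample(c("A", "C", "G", "T"), 16, replace = TRUE)
  inv <- c(T = "A", A = "T", G = "C", C = "G")
  for (j in 0:15) {
    sc_chars[50 - j + 1L] <- inv[[stc[j + 1L]]]
    sc_chars[180 - j + 1L] <- inv[[stc[j + 1L]]]
  }
  sc <- scaffold(paste(sc_chars, collapse = ""), circular = FALSE)
  v <- list(vid = 0L, parent_id = 0L, parent_segment_index = 0L,
            offset = 0L, chars = stc, length = 16L)
  srt <- build_srt(v, sc, 6L, sigma = 16L)
  expect_gte(length(srt$routes), 2L)
  full <- srt$routes[(vapply(srt$routes, function(r)
    nrow(r$sections), integer(1)) == 1L)]
  expect_length(intersect(full[[1]]$bases, full[[2]]$bases), 0L)
  # general property: footprint is contained in every route's base set
  fp <- footprint(srt)
  for (r in srt$routes) expect_true(all(fp %in% r$bases))
  expect_equal(sort(fp), sort(Reduce(intersect,
                                     lapply(srt$routes, `[[`, "bases"))))
})

test_that("route_stats matches brute-force enumeration counts", {
  fd <- small_fixture(1, rows = 2, cols = 40, section_len = 8)
  sc <- fd$design$scaffold
  vs <- split_virtual(fd$design)
  srts <- lapply(vs, build_srt, sc = sc, mu_min = 6L, sigma = 40L)
  stats <- route_stats(srts)
  oracle_nr <- vapply(vs, function(v) {
    length(oracle_routes(v$chars, sc$chars, 6L, sc$circular, sc$material))
  }, integer(1))
  expect_equal(stats$n_one_route, sum(oracle_nr == 1L))
  expect_equal(stats$n_multi_route, sum(oracle_nr > 1L))
  expect_equal(stats$max_routes, max(oracle_nr))
  if (stats$n_multi_route > 0) {
    expect_equal(stats$mean_routes_multi, mean(oracle_nr[oracle_nr > 1L]))
  }
  # all one-route: multi-route mean reported as 0 count
  s1 <- route_stats(lapply(vs[1:2], build_srt, sc = sc, mu_min = 8L,
                           sigma = 0L))
  if (s1$n_multi_route == 0L) expect_equal(s1$mean_routes_multi, 0)
})

test_that("the tree-size guard aborts pathological staples gracefully", {
  sc <- scaffold(strrep("AT", 150))
  v <- list(vid = 0L, parent_id = 0L, parent_segment_index = 0L,
            offset = 0L, chars = rep(c("A", "T"), 10), length = 20L)
  srt <- build_srt(v, sc, 4L, sigma = 20L, max_nodes = 50)
  expect_true(srt$aborted)
  expect_length(srt$routes, 0L)
})
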