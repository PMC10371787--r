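test_that("hamming distance equals the positionwise brute count", {
  sc <- scaffold(strrep("ACGT", 25))
  for (seed in 1:5) {
    g <- random_map(sc, seed = seed)
    r <- random_map(sc, seed = seed + 100)
    expect_equal(hamming(g, r), oracle_hamming(g, r))
  }
})

test_that("hamming is a metric on contact maps over a fixed scaffold", {
  sc <- scaffold(strrep("ACGT", 25))
  a <- random_map(sc, seed = 1)
  b <- random_map(sc, seed = 2)
  c_ <- random_map(sc, seed = 3)
  expect_equal(hamming(a, a), 0L)                       # identity
  expect_equal(hamming(a, b), hamming(b, a))            # symmetry
  expect_lte(hamming(a, c_), hamming(a, b) + hamming(b, c_))  # triangle
  sc2 <- scaffold(strrep("ACGT", 10))
  expect_error(hamming(a, random_map(sc2)), "length")
})

test_that("a junction skewed by one base contributes exactly the skew", {
  # one 32-nt staple designed 16-16; the recovered map splits it 17-15
  sc <- scaffold(strrep("ACGT", 60), circular = FALSE)
  n <- sc$n
  g_ps <- rep(NA_integer_, n); g_pb <- rep(NA_integer_, n)
  s1 <- 100L; s2 <- 200L
  g_ps[(s1 - 0:15) + 1L] <- 0L; g_pb[(s1 - 0:15) + 1L] <- 0:15
  g_ps[(s2 - 0:15) + 1L] <- 0L; g_pb[(s2 - 0:15) + 1L] <- 16:31
  r_ps <- rep(NA_integer_, n); r_pb <- rep(NA_integer_, n)
  r_ps[(s1 - 0:16) + 1L] <- 0L; r_pb[(s1 - 0:16) + 1L] <- 0:16
  r_ps[(s2 - 1L - 0:14) + 1L] <- 0L; r_pb[(s2 - 1L - 0:14) + 1L] <- 17:31
  g <- contact_map(g_ps, g_pb, sc)
  r <- contact_map(r_ps, r_pb, sc)
  # substituted bases: exactly the overshot base (paired in r, unpaired in
  # g) and the orphaned base at the second section's 5' side; the shifted
  # second section re-pairs identically base for base
  expect_equal(hamming(g, r), oracle_hamming(g, r))
  expect_equal(hamming(g, r), 2L)
  expect_gt(hamming(g, r), 0L)               # a skew always raises d
})

test_that("degenerate scaffolds give the degenerate domain graphs", {
  sc_c <- scaffold(strrep("ACGT", 10), circular = TRUE)
  empty_c <- contact_map(rep(NA_integer_, 40), rep(NA_integer_, 40), sc_c)
  D <- to_domain_graph(empty_c)
  expect_equal(D$edges$type, "ss_scaffold")
  expect_equal(D$edges$length, 40L)

  sc_l <- scaffold(strrep("ACGT", 10), circular = FALSE)
  empty_l <- contact_map(rep(NA_integer_, 40), rep(NA_integer_, 40), sc_l)
  Dl <- to_domain_graph(empty_l)
  expect_setequal(Dl$edges$type, c("ss_scaffold", "scaffold_nick"))
})

test_that("a two-section staple yields 2 ds edges and 1 crossover", {
  sc <- scaffold(strrep("ACGT", 30), circular = FALSE)
  ps <- rep(NA_integer_, 120); pb <- rep(NA_integer_, 120)
  ps[(20 - 0:7) + 1L] <- 0L; pb[(20 - 0:7) + 1L] <- 0:7
  ps[(60 - 0:7) + 1L] <- 0L; pb[(60 - 0:7) + 1L] <- 8:15
  cm <- contact_map(ps, pb, sc)
  D <- to_domain_graph(cm)
  expect_equal(sum(D$edges$type == "ds_scaffold"), 2L)
  expect_equal(sum(D$edges$type == "staple_crossover"), 1L)
  xo <- D$edges[D$edges$type == "staple_crossover", ]
  expect_equal(xo$from, "13")    # 3' end of first section
  expect_equal(xo$to, "61")      # boundary past the second section's 5' end
  # ds + ss edge base counts partition the scaffold
  expect_equal(sum(D$edges$length[D$edges$type %in%
                                    c("ds_scaffold", "ss_scaffold")]), 120L)
})

test_that("loop-outs and dangles are typed from the staple markup", {
  fd <- small_fixture(13)
  st <- fd$design$staples
  # splice a loop-out into staple 0 and dangles onto staple 1
  s0 <- st[[1]]$sequence
  st[[1]] <- staple(paste0(substr(s0, 1, 8), "tttt", substr(s0, 9, 16)), 0L)
  st[[2]] <- staple(paste0("aaa", st[[2]]$sequence, "gg"), 1L)
  des <- design(fd$design$scaffold, st)
  res <- solve_design(des, solver_params())
  D <- to_domain_graph(res$contact_map, des)
  expect_gte(sum(D$edges$type == "staple_loopout"), 1L)
  lo <- D$edges[D$edges$type == "staple_loopout", ][1, ]
  expect_equal(lo$length, 4L)
  dg <- D$edges[D$edges$type == "staple_dangle", ]
  expect_setequal(dg$length, c(3L, 2L))
  expect_true(all(grepl("^d1\\.", c(dg$from, dg$to))[
    grepl("^d", c(dg$from, dg$to))]))
})

test_that("domain graph and contact map are mutually inverse", {
  for (seed in c(1, 9)) {
    fd <- small_fixture(seed, rows = 4, cols = 48, extra_scaffold = 13)
    cm <- solve_design(fd$design, solver_params())$contact_map
    D <- to_domain_graph(cm, fd$design)
    cm2 <- from_domain_graph(D, fd$design$scaffold)
    expect_equal(hamming(cm, cm2), 0L)
    expect_identical(cm$partner_staple, cm2$partner_staple)
    expect_identical(cm$partner_base, cm2$partner_base)
  }
  # empty design round-trips too
  sc <- scaffold("ACGTACGT")
  empty <- contact_map(rep(NA_integer_, 8), rep(NA_integer_, 8), sc)
  expect_equal(hamming(from_domain_graph(to_domain_graph(empty), sc),
                       empty), 0L)
})

test_that("an inconsistent contact map is rejected", {
  fd <- small_fixture(2)
  # mutate one paired scaffold letter so the recorded partner no longer
  # complements the sequence
  ch <- fd$design$scaffold$chars
  w <- which(!is.na(fd$truth$partner_staple))[1]
  ch[w] <- setdiff(c("A", "C", "G", "T"), ch[w])[1]
  sc2 <- scaffold(paste(ch, collapse = ""))
  des2 <- design(sc2, fd$design$staples)
  bad <- contact_map(fd$truth$partner_staple, fd$truth$partner_base, sc2)
  expect_error(to_domain_graph(bad, des2), "inconsistent")
})

test_that("contact map CSV and domain graph JSON round-trip", {
  fd <- small_fixture(7)
  cm <- fd$truth
  f <- tempfile(fileext = ".csv")
  write_contact_map(cm, f)
  cm2 <- read_contact_map(f, fd$design$scaffold)
  expect_identical(cm$partner_staple, cm2$partner_staple)
  expect_identical(cm$partner_base, cm2$partner_base)

  D <- to_domain_graph(cm, fd$design)
  g <- tempfile(fileext = ".json")
  write_domain_graph(D, g)
  D2 <- read_domain_graph(g)
  expect_equal(D2$n, D$n)
  expect_equal(D2$edges$type, D$edges$type)
  expect_equal(D2$edges$length, D$edges$length)
  expect_equal(hamming(from_domain_graph(D2, fd$design$scaffold), cm), 0L)
})
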