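# Independent brute-force oracles.  These deliberately share no code with
# the package internals: pairing is re-derived from an explicit lookup
# table, matching is a position-by-position scan, route enumeration is
# plain recursion with no sibling pruning, and junction slack is an
# explicit re-pairing check of a shifted contact map.

oracle_pair_table <- function(material) {
  if (material == "DNA") {
    c(A = "T", T = "A", C = "G", G = "C")
  } else {
    c(A = "T", U = "A", C = "G", G = "C")   # DNA staples on RNA scaffold
  }
}

# every (start, mu) where the suffix's first >= mu_min bases pair
# antiparallel with the scaffold, extended greedily to the maximal run
oracle_matches <- function(suffix, sc_chars, mu_min, circular, material) {
  tab <- oracle_pair_table(material)
  n <- length(sc_chars)
  L <- length(suffix)
  out <- list()
  for (s in seq_len(n) - 1L) {
    mu <- 0L
    repeat {
      b <- s - mu
      if (b < 0L) {
        if (!circular) break
        b <- b + n
      }
      if (mu >= L) break
      if (tab[[sc_chars[b + 1L]]] == suffix[mu + 1L]) mu <- mu + 1L else break
    }
    if (mu >= mu_min) out[[length(out) + 1L]] <- c(start = s, mu = mu)
  }
  out
}

# exhaustive enumeration of complete maximal-run tilings of a staple
# (self-overlap within a route forbidden, adjacency allowed); returns a
# character vector of route signatures "start:mu|start:mu|..."
oracle_routes <- function(staple_chars, sc_chars, mu_min, circular, material) {
  n <- length(sc_chars)
  sigs <- character(0)
  rec <- function(offset, used, sig) {
    L <- length(staple_chars)
    if (offset == L) {
      sigs[[length(sigs) + 1L]] <<- paste(sig, collapse = "|")
      return(invisible())
    }
    mm <- oracle_matches(staple_chars[(offset + 1L):L], sc_chars, mu_min,
                         circular, material)
    for (m in mm) {
      b <- m[["start"]] - 0:(m[["mu"]] - 1L)
      if (circular) b <- b %% n
      if (any(b < 0L) || any(b %in% used)) next
      rec(offset + m[["mu"]], c(used, b),
          c(sig, sprintf("%d:%d", m[["start"]], m[["mu"]])))
    }
  }
  rec(0L, integer(0), character(0))
  sort(sigs)
}

route_signatures <- function(srt) {
  sort(vapply(srt$routes, function(r) {
    paste(sprintf("%d:%d", r$sections[, "start"], r$sections[, "mu"]),
          collapse = "|")
  }, character(1)))
}

# explicit re-pairing slack oracle: shift the junction boundary base by
# base and re-check full Watson-Crick complementarity of every transferred
# base against the fixed staple sequences
oracle_slack <- function(cm, des, b, dir) {
  n <- cm$n
  tab <- oracle_pair_table(des$scaffold$material)
  sc_chars <- des$scaffold$chars
  wrap <- function(i) if (cm$circular) i %% n else i
  b2 <- wrap(b + 1L)
  # flanking section lengths by direct scan
  flank <- function(start, dir) {
    len <- 1L
    cur <- start
    repeat {
      nxt <- wrap(cur + dir)
      if (!cm$circular && (cur + dir < 0L || cur + dir >= n)) break
      same <- !is.na(cm$partner_staple[nxt + 1L]) &&
        cm$partner_staple[nxt + 1L] == cm$partner_staple[cur + 1L] &&
        cm$partner_base[nxt + 1L] == cm$partner_base[cur + 1L] - dir
      if (!same) break
      cur <- nxt; len <- len + 1L
      if (len > n) break
    }
    len
  }
  cap <- min(flank(b, -1L), flank(b2, +1L)) - 1L
  if (cap < 1L) return(0L)
  taker <- if (dir > 0) cm$partner_staple[b + 1L] else cm$partner_staple[b2 + 1L]
  tk <- des$staples[[taker + 1L]]
  slack <- 0L
  for (k in seq_len(cap)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      pos <- if (dir > 0) wrap(b + j) else wrap(b - j + 1L)
      if (pos < 0L || pos >= n) { ok <- FALSE; break }
      sb <- if (dir > 0) cm$partner_base[b + 1L] - j else
        cm$partner_base[b2 + 1L] + j
      if (sb < 0L || sb >= tk$length) { ok <- FALSE; break }
      if (tab[[sc_chars[pos + 1L]]] != tk$chars[sb + 1L]) { ok <- FALSE; break }
    }
    if (!ok) break
    slack <- k
  }
  slack
}

# positionwise mismatch count between two contact maps
oracle_hamming <- function(g, r) {
  cnt <- 0L
  for (i in seq_len(g$n)) {
    gp <- c(g$partner_staple[i], g$partner_base[i])
    rp <- c(r$partner_staple[i], r$partner_base[i])
    if (all(is.na(gp)) && all(is.na(rp))) next
    if (any(is.na(gp)) != any(is.na(rp)) || any(gp != rp)) cnt <- cnt + 1L
  }
  cnt
}

# random contact map over a scaffold (for metric property checks)
random_map <- function(sc, n_staples = 4L, seed = 1L) {
  set.seed(seed)
  ps <- rep(NA_integer_, sc$n); pb <- rep(NA_integer_, sc$n)
  for (s in seq_len(n_staples) - 1L) {
    len <- sample(4:10, 1L)
    start <- sample(0:(sc$n - len), 1L)
    idx <- start:(start + len - 1L)
    free <- is.na(ps[idx + 1L])
    ps[idx + 1L][free] <- s
    pb[idx + 1L][free] <- which(free) - 1L
  }
  # ensure (staple, base) uniqueness by renumbering bases per staple
  for (s in unique(stats::na.omit(ps))) {
    w <- which(!is.na(ps) & ps == s)
    pb[w] <- seq_along(w) - 1L
  }
  contact_map(ps, pb, sc)
}

# small random design: raster fixture on a random scaffold, optionally with
# unhardened junctions
small_fixture <- function(seed, rows = 2L, cols = 48L, section_len = 8L,
                          hardened = TRUE, kind = "random", ...) {
  forward_design(rows, cols, section_len = section_len,
                 scaffold_kind = kind, seed = seed,
                 junction_distinct = hardened, ...)
}
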