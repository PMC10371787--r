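# Forward-design fixture generator: raster origami designs with known
# ground-truth contact maps, so every pipeline stage is testable without any
# external sequence data.

.debruijn_cache <- new.env(parent = emptyenv())

#' Repeat-deficient scaffold sequence (De Bruijn prefix)
#'
#' Returns a prefix of an order-`k` De Bruijn cycle over `{A,C,G,T}`: every
#' k-mer occurs at most once in the returned sequence, so staple sections of
#' `k` bases or more have unique scaffold matches.  Maximum length is
#' `4^k + k - 1` (the linearised cycle).
#'
#' @param k De Bruijn order (k-mer size), a positive integer.
#' @param length Sequence length in bases.
#' @param rotate Rotation of the underlying cycle (0 to `4^k - 1`): any
#'   rotation is equally repeat-deficient, which gives a family of distinct
#'   scaffolds with identical uniqueness guarantees.
#' @return Character scalar.
#' @export
debruijn_sequence <- function(k, length, rotate = 0L) {
  stopifnot(k >= 1, length >= 1)
  if (length > 4^k + k - 1) {
    stop(sprintf("length %d too large for order %d (max %d)",
                 length, k, 4^k + k - 1))
  }
  key <- as.character(k)
  if (is.null(.debruijn_cache[[key]])) {
    # standard Lyndon-word ("FKM") construction of the De Bruijn cycle
    a <- integer(k + 1L)
    seqv <- integer(0)
    out <- new.env(parent = emptyenv()); out$v <- vector("list", 4096); out$i <- 0L
    db <- function(t, p) {
      if (t > k) {
        if (k %% p == 0L) {
          out$i <- out$i + 1L
          if (out$i > length(out$v)) out$v <- c(out$v, vector("list", length(out$v)))
          out$v[[out$i]] <- a[2:(p + 1L)]
        }
      } else {
        a[t + 1L] <<- a[t - p + 1L]
        db(t + 1L, p)
        j <- a[t - p + 1L] + 1L
        while (j <= 3L) {
          a[t + 1L] <<- j
          db(t + 1L, t)
          j <- j + 1L
        }
      }
    }
    db(1L, 1L)
    .debruijn_cache[[key]] <- unlist(out$v[seq_len(out$i)])
  }
  cyc <- .debruijn_cache[[key]]
  rotate <- as.integer(rotate) %% length(cyc)
  if (rotate > 0L) cyc <- c(cyc[(rotate + 1L):length(cyc)], cyc[1:rotate])
  lin <- c(cyc, cyc[seq_len(k - 1L)])       # linearised cycle
  paste(DNA_ALPHABET[lin[seq_len(length)] + 1L], collapse = "")
}

# Scaffold index of grid cell (row r, column c), 0-based, under the
# serpentine raster path: even rows run left->right, odd rows right->left.
raster_index <- function(r, c, cols) {
  if (r %% 2L == 0L) r * cols + c else r * cols + (cols - 1L - c)
}

#' Generate a raster origami design with ground truth
#'
#' Lays a serpentine scaffold path over a `rows x cols` grid and tiles it
#' with staples of `n_sections` equal sections of `section_len` bases.  Each
#' staple binds a column block across `n_sections` adjacent rows, crossing
#' over at alternating block edges, with every section running antiparallel
#' to the scaffold.  Staple sequences are derived as Watson-Crick partners of
#' their scaffold bases, so the emitted ground-truth contact map is exact by
#' construction.
#'
#' @param rows Helix rows; must be a multiple of `n_sections`.
#' @param cols Bases per row; must be a multiple of `section_len`.
#' @param section_len Bases per staple section (default 16, the classic
#'   32-nt two-section raster staple).
#' @param n_sections Sections per staple (default 2).
#' @param scaffold_kind `"random"` (seeded i.i.d. bases), `"debruijn"`
#'   (repeat-deficient, order `debruijn_k`), or `"provided"`.
#' @param debruijn_k De Bruijn order when `scaffold_kind = "debruijn"`.
#' @param provided_sequence Scaffold sequence when `scaffold_kind = "provided"`;
#'   must cover the grid plus `extra_scaffold`.
#' @param extra_scaffold Unpaired scaffold bases appended after the grid
#'   (a single-stranded loop/tail, common in real origami); default 0.
#' @param circular Scaffold circularity (default `TRUE`).
#' @param material Scaffold material.
#' @param seed Integer seed for random scaffolds.
#' @param junction_distinct If `TRUE` (the default), post-edit the scaffold
#'   so that the scaffold letter on one side of every junction differs from
#'   the letter that would allow the junction to migrate, making every
#'   junction sequence-immovable and every designed section's greedy match
#'   overshoot-free (staples are re-derived afterwards).  This is the
#'   sequence-engineering rule a well-designed origami follows so that its
#'   topology is unambiguously encoded in its sequences; set `FALSE` to
#'   emulate designs without it (skewed-junction defects become possible).
#' @return List with `design` (an [design()] object) and `truth` (the
#'   ground-truth [contact_map()]).
#' @export
forward_design <- function(rows, cols, section_len = 16L, n_sections = 2L,
                           scaffold_kind = c("random", "debruijn", "provided"),
                           debruijn_k = 7L, provided_sequence = NULL,
                           extra_scaffold = 0L, circular = TRUE,
                           material = c("DNA", "RNA"), seed = 1L,
                           junction_distinct = TRUE) {
  scaffold_kind <- match.arg(scaffold_kind)
  material <- match.arg(material)
  rows <- as.integer(rows); cols <- as.integer(cols)
  section_len <- as.integer(section_len); n_sections <- as.integer(n_sections)
  if (rows < 1L || cols < 1L) stop("grid must be non-empty")
  if (rows %% n_sections != 0L) stop("rows must be a multiple of n_sections")
  if (cols %% section_len != 0L) stop("cols must be a multiple of section_len")
  n_grid <- rows * cols
  n <- n_grid + as.integer(extra_scaffold)

  alpha <- if (material == "DNA") DNA_ALPHABET else RNA_ALPHABET
  sc_chars <- switch(scaffold_kind,
    random = {
      set.seed(seed)
      sample(alpha, n, replace = TRUE)
    },
    debruijn = {
      if (material != "DNA") stop("debruijn scaffolds are generated as DNA")
      set.seed(seed)
      rot <- sample.int(4^debruijn_k, 1L) - 1L
      strsplit(debruijn_sequence(debruijn_k, n, rotate = rot), "")[[1]]
    },
    provided = {
      s <- toupper(gsub("[[:space:]]", "", provided_sequence))
      if (nchar(s) < n) stop("provided scaffold shorter than the grid")
      strsplit(substr(s, 1L, n), "")[[1]]
    }
  )

  # ordered scaffold bases traversed by each staple, 5'->3'
  staple_paths <- list()
  groups <- rows %/% n_sections
  blocks <- cols %/% section_len
  for (g in seq_len(groups) - 1L) {
    for (j in seq_len(blocks) - 1L) {
      c0 <- j * section_len
      c1 <- c0 + section_len - 1L
      path <- integer(0)
      for (t in seq_len(n_sections) - 1L) {
        r <- g * n_sections + t
        cs <- if (r %% 2L == 0L) c1:c0 else c0:c1   # scaffold-decreasing
        path <- c(path, raster_index(r, cs, cols))
      }
      staple_paths[[length(staple_paths) + 1L]] <- path
    }
  }

  if (junction_distinct) {
    sc_chars <- enforce_distinct_junctions(sc_chars, staple_paths,
                                           section_len, n, circular)
  }

  sc <- scaffold(paste(sc_chars, collapse = ""), circular = circular,
                 material = material)
  staples <- lapply(seq_along(staple_paths), function(i) {
    staple(paste(sc$req[staple_paths[[i]] + 1L], collapse = ""), id = i - 1L)
  })
  des <- design(sc, staples)

  partner_staple <- rep(NA_integer_, n)
  partner_base <- rep(NA_integer_, n)
  for (i in seq_along(staple_paths)) {
    p <- staple_paths[[i]]
    partner_staple[p + 1L] <- i - 1L
    partner_base[p + 1L] <- seq_along(p) - 1L
  }
  truth <- contact_map(partner_staple, partner_base, sc)
  list(design = des, truth = truth)
}

# Mutate scaffold letters so every junction is sequence-immovable.  For the
# boundary b|b+1 between two different staple sections, migration one base to
# the right requires scaffold[b+1] to equal the scaffold letter paired by the
# left staple's preceding base (and symmetrically to the left).  Collect all
# such equality constraints as "must differ" pairs and greedily recolour.
enforce_distinct_junctions <- function(sc_chars, staple_paths, section_len,
                                       n, circular) {
  # partner bookkeeping on the grid part
  pstaple <- rep(NA_integer_, n); pbase <- rep(NA_integer_, n)
  for (i in seq_along(staple_paths)) {
    p <- staple_paths[[i]]
    pstaple[p + 1L] <- i - 1L
    pbase[p + 1L] <- seq_along(p) - 1L
  }
  pairs <- list()
  # overshoot guards: for every consecutive section pair of every staple,
  # the scaffold letter 5'-ward of a section's run must differ from the
  # letter at the next section's start, even when that base is unpaired
  # (e.g. a single-stranded tail) -- greedy matching must stop exactly at
  # the designed junction
  for (p in staple_paths) {
    n_sec <- length(p) %/% section_len
    for (t in seq_len(n_sec - 1L)) {
      e <- p[t * section_len]               # last base of section t's run
      u <- if (circular) (e - 1L) %% n else e - 1L
      if (u < 0L) next
      v <- p[t * section_len + 1L]          # start of section t+1
      pairs[[length(pairs) + 1L]] <- c(u, v)
    }
  }
  last_b <- if (circular) n - 1L else n - 2L
  for (b in 0:last_b) {
    b2 <- (b + 1L) %% n
    if (is.na(pstaple[b + 1L]) || is.na(pstaple[b2 + 1L])) next
    same_sec <- pstaple[b + 1L] == pstaple[b2 + 1L] &&
      pbase[b2 + 1L] == pbase[b + 1L] - 1L
    if (same_sec) next
    # right migration: left staple X (at b) extends using its base p-1
    x <- pstaple[b + 1L]; p <- pbase[b + 1L]
    if (p >= 1L) {
      u <- staple_paths[[x + 1L]][p]      # scaffold base paired by X base p-1
      pairs[[length(pairs) + 1L]] <- c(b2, u)
    }
    # left migration: right staple Y (at b+1) extends using its base q+1
    y <- pstaple[b2 + 1L]; q <- pbase[b2 + 1L]
    if (q + 1L < length(staple_paths[[y + 1L]])) {
      v <- staple_paths[[y + 1L]][q + 2L]
      pairs[[length(pairs) + 1L]] <- c(b, v)
    }
  }
  if (length(pairs) == 0L) return(sc_chars)
  m <- do.call(rbind, pairs)
  for (pass in 1:8) {
    conflict <- sc_chars[m[, 1] + 1L] == sc_chars[m[, 2] + 1L]
    if (!any(conflict)) break
    for (i in which(conflict)) {
      v <- m[i, 2]
      partners <- c(m[m[, 1] == v, 2], m[m[, 2] == v, 1])
      forbidden <- unique(sc_chars[partners + 1L])
      choice <- setdiff(DNA_ALPHABET, forbidden)
      if (length(choice) > 0L) sc_chars[v + 1L] <- choice[[1]]
    }
  }
  sc_chars
}

#' Test a sequence for k-mer uniqueness
#'
#' `TRUE` when every k-mer occurs at most once (for circular sequences the
#' origin-spanning k-mers are included).  Used to assert the repeat-free
#' premise of fixtures whose only intended repeat is an implanted decoy:
#' the junction-hardening scaffold edits of [forward_design()] can
#' occasionally recreate a duplicate k-mer on an otherwise De Bruijn
#' scaffold.
#'
#' @param sequence Character scalar.
#' @param k k-mer size.
#' @param circular Include wrap-around k-mers.
#' @export
has_unique_kmers <- function(sequence, k, circular = TRUE) {
  s <- if (circular) paste0(sequence, substr(sequence, 1L, k - 1L)) else
    sequence
  n <- nchar(s)
  if (n < k) return(TRUE)
  anyDuplicated(substring(s, 1:(n - k + 1L), k:n)) == 0L
}

#' Implant a decoy binding site in the single-stranded scaffold tail
#'
#' Overwrites part of the unpaired scaffold tail of a [forward_design()]
#' fixture (made with `extra_scaffold > decoy_len + 1`) so that the first
#' `decoy_len` bases of one staple find a single contiguous antiparallel
#' match there -- longer than the staple's true first section, so a solver
#' that greedily commits the longest match is lured away from the designed
#' route, while a solver requiring a complete route tiling is not (the
#' decoy leaves a remainder below any sensible minimum section length).
#' The base 5'-ward of the decoy is forced to mismatch so the decoy run is
#' maximal at exactly `decoy_len`.
#'
#' @param fd Result of [forward_design()] (list with `design`, `truth`).
#' @param staple_id Staple to lure (default 0).
#' @param decoy_len Bases of the staple 5' prefix replicated (default 12).
#' @return The modified `fd` (same ground truth; scaffold edited only in
#'   unpaired tail positions).
#' @export
implant_decoy <- function(fd, staple_id = 0L, decoy_len = 12L) {
  des <- fd$design
  sc <- des$scaffold
  unpaired <- which(is.na(fd$truth$partner_staple)) - 1L
  if (length(unpaired) < decoy_len + 2L) {
    stop("fixture needs an unpaired scaffold tail of at least decoy_len + 2 bases")
  }
  st <- des$staples[[staple_id + 1L]]
  chars <- sc$chars
  alpha <- if (sc$material == "DNA") DNA_ALPHABET else RNA_ALPHABET
  # scaffold letter paired by a given staple letter (inverse of wc_partner)
  inv <- stats::setNames(alpha, wc_partner(alpha, sc$material))
  t0 <- unpaired[2L]                        # leave unpaired[1] as mismatch guard
  # staple base j must pair scaffold base t0 + decoy_len - 1 - j
  for (j in seq_len(decoy_len) - 1L) {
    chars[t0 + decoy_len - 1L - j + 1L] <- inv[[st$chars[j + 1L]]]
  }
  # ensure mismatch one base 5'-ward of the decoy (guards maximality)
  guard <- t0 - 1L
  if (decoy_len < st$length) {
    bad <- inv[[st$chars[decoy_len + 1L]]]
    if (chars[guard + 1L] == bad) chars[guard + 1L] <- setdiff(alpha, bad)[1L]
  }
  sc2 <- scaffold(paste(chars, collapse = ""), circular = sc$circular,
                  material = sc$material)
  fd$design <- design(sc2, des$staples)
  fd$truth <- contact_map(fd$truth$partner_staple, fd$truth$partner_base, sc2)
  fd
}

#' Add input noise to a design
#'
#' Emulates imperfectly transcribed staple lists: per-base substitutions on
#' staple sequences and/or surplus random "contaminant" staples, appended at
#' the end of the staple list or shuffled into it.
#'
#' @param design An [design()] object.
#' @param sub_rate Per-base substitution probability on staples (scaffold
#'   untouched).
#' @param n_contaminants Number of surplus random DNA staples.
#' @param contaminant_len Length of each contaminant.
#' @param position `"end"` (original ids unchanged) or `"shuffled"` (ids
#'   reassigned from the new order).
#' @param seed Integer seed.
#' @return A new [design()] object.
#' @export
add_noise <- function(design, sub_rate = 0, n_contaminants = 0L,
                      contaminant_len = 32L, position = c("end", "shuffled"),
                      seed = 1L) {
  position <- match.arg(position)
  set.seed(seed)
  seqs <- vapply(design$staples, function(s) s$sequence, character(1))
  if (sub_rate > 0) {
    seqs <- vapply(seqs, function(sq) {
      ch <- strsplit(sq, "")[[1]]
      hit <- stats::runif(length(ch)) < sub_rate
      for (i in which(hit)) {
        up <- toupper(ch[i])
        repl <- sample(setdiff(DNA_ALPHABET, up), 1L)
        ch[i] <- if (ch[i] == up) repl else tolower(repl)
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  if (n_contaminants > 0L) {
    cont <- vapply(seq_len(n_contaminants), function(i) {
      paste(sample(DNA_ALPHABET, contaminant_len, replace = TRUE),
            collapse = "")
    }, character(1))
    seqs <- if (position == "end") c(seqs, cont) else sample(c(seqs, cont))
  }
  staples <- lapply(seq_along(seqs), function(i) staple(seqs[[i]], id = i - 1L))
  design(design$scaffold, staples)
}
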