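#' @keywords internal
"_PACKAGE"

# Scaffold base indices are 0-based from the 5' end throughout the package,
# matching the (start_base: length) notation used in solver reports.  They are
# converted to R's 1-based indexing only at the point of vector access.

DNA_ALPHABET <- c("A", "C", "G", "T")
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Construct a scaffold strand
#'
#' The scaffold is the single long strand of an origami.  Its sequence is
#' stored 5'->3'; indexing is 0-based from the 5' end.  Circular scaffolds
#' (e.g. M13mp18-derived) wrap modulo their length; linear scaffolds never
#' wrap.
#'
#' @param sequence Character scalar over `A,C,G,T` (DNA) or `A,C,G,U` (RNA).
#'   Case is ignored (scaffolds carry no markup).
#' @param circular Logical; default `TRUE` (M13-like).
#' @param material `"DNA"` or `"RNA"`.  Staples are always DNA; an RNA
#'   scaffold with DNA staples is a hybrid origami.
#' @return An object of class `origami_scaffold` with fields `sequence`,
#'   `chars`, `req` (the staple base required to pair each scaffold base),
#'   `n`, `circular`, `material`.
#' @export
scaffold <- function(sequence, circular = TRUE, material = c("DNA", "RNA")) {
  material <- match.arg(material)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) == 0L) stop("empty scaffold sequence")
  chars <- strsplit(sequence, "")[[1]]
  alpha <- if (material == "DNA") DNA_ALPHABET else RNA_ALPHABET
  bad <- setdiff(unique(chars), alpha)
  if (length(bad) > 0L) {
    stop(sprintf("illegal scaffold base(s) %s for material %s",
                 paste(bad, collapse = ","), material))
  }
  structure(list(
    sequence = sequence,
    chars    = chars,
    req      = wc_partner(chars, material),
    n        = length(chars),
    circular = isTRUE(circular),
    material = material
  ), class = "origami_scaffold")
}

#' @export
print.origami_scaffold <- function(x, ...) {
  cat(sprintf("<scaffold> %d nt %s, %s\n", x$n, x$material,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Watson-Crick staple partner of a scaffold base
#'
#' Returns, for each scaffold base, the staple base letter that hybridises it.
#' Staples are DNA in all supported origami classes, so for an RNA scaffold
#' the hybrid pairing rule applies: scaffold U pairs staple A, scaffold A
#' pairs staple T, C/G pair as usual.
#'
#' @param base Character vector of single bases.
#' @param material Scaffold material, `"DNA"` or `"RNA"`.
#' @return Character vector of staple base letters.
#' @export
wc_partner <- function(base, material = c("DNA", "RNA")) {
  material <- match.arg(material)
  map <- if (material == "DNA") {
    c(A = "T", C = "G", G = "C", T = "A")
  } else {
    c(A = "T", C = "G", G = "C", U = "A")
  }
  out <- map[base]
  if (anyNA(out)) stop("unknown base: ", paste(unique(base[is.na(out)]), collapse = ","))
  unname(out)
}

#' Watson-Crick complement within one material
#'
#' Classic complement (an involution): DNA A<->T, C<->G; RNA A<->U, C<->G.
#' For the staple-vs-scaffold pairing test use [wc_partner()], which encodes
#' the hybrid rule.
#'
#' @inheritParams wc_partner
#' @export
wc_complement <- function(base, material = c("DNA", "RNA")) {
  material <- match.arg(material)
  map <- if (material == "DNA") {
    c(A = "T", C = "G", G = "C", T = "A")
  } else {
    c(A = "U", C = "G", G = "C", U = "A")
  }
  out <- map[base]
  if (anyNA(out)) stop("unknown base: ", paste(unique(base[is.na(out)]), collapse = ","))
  unname(out)
}

# Run-length segmentation of a marked-up staple sequence.  Lowercase letters
# denote non-hybridising subsequences (end dangles, interior loop-outs);
# uppercase letters are hybridising.  Returns a data.frame with 0-based
# `start` (staple base index), `length`, and `kind`.
staple_segments <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  hyb <- chars %in% c(LETTERS)
  r <- rle(hyb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(
    kind   = ifelse(r$values, "hybridising", "nonhybridising"),
    start  = as.integer(starts),
    length = as.integer(r$lengths),
    stringsAsFactors = FALSE
  )
}

#' Construct a staple strand
#'
#' Staple sequences are written 5'->3'.  Lowercase letters mark
#' non-hybridising subsequences (dangles at either end, interior loop-outs);
#' these are never routed on the scaffold.  A staple without markup has a
#' single hybridising segment covering its whole sequence.
#'
#' @param sequence Character scalar over `A,C,G,T` (either case).
#' @param id Integer staple id; 0-based position in the input list.
#' @return An object of class `origami_staple`.
#' @export
staple <- function(sequence, id = 0L) {
  sequence <- gsub("[[:space:]]", "", sequence)
  if (nchar(sequence) == 0L) stop("empty staple sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("illegal staple base(s) %s (staples are DNA)",
                 paste(bad, collapse = ",")))
  }
  structure(list(
    id       = as.integer(id),
    sequence = sequence,
    chars    = chars,               # uppercase letters, full staple
    length   = length(chars),
    segments = staple_segments(sequence)
  ), class = "origami_staple")
}

#' @export
print.origami_staple <- function(x, ...) {
  nh <- sum(x$segments$kind == "nonhybridising")
  cat(sprintf("<staple %d> %d nt, %d segment(s)%s\n", x$id, x$length,
              nrow(x$segments),
              if (nh) sprintf(" (%d non-hybridising)", nh) else ""))
  invisible(x)
}

#' Bundle a scaffold and staple list into a design
#'
#' @param scaffold An [scaffold()] object.
#' @param staples List of [staple()] objects; ids must be unique and dense
#'   from 0 (input-file line order).
#' @return An object of class `origami_design`.
#' @export
design <- function(scaffold, staples) {
  stopifnot(inherits(scaffold, "origami_scaffold"))
  ids <- vapply(staples, function(s) s$id, integer(1))
  if (length(ids) > 0L && !identical(sort(ids), seq_along(ids) - 1L)) {
    stop("staple ids must be unique and dense from 0")
  }
  too_long <- vapply(staples, function(s) s$length > scaffold$n, logical(1))
  if (any(too_long)) {
    stop("staple(s) ", paste(ids[too_long], collapse = ","),
         " longer than the scaffold")
  }
  staples <- staples[order(ids)]
  structure(list(scaffold = scaffold, staples = staples),
            class = "origami_design")
}

#' @export
print.origami_design <- function(x, ...) {
  print(x$scaffold)
  cat(sprintf("  %d staples (%d nt total)\n", length(x$staples),
              sum(vapply(x$staples, function(s) s$length, integer(1)))))
  invisible(x)
}

# Read one sequence from a FASTA file (first record) or a bare-sequence file.
read_sequence_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) == 0L) stop("empty sequence file: ", path)
  if (startsWith(lines[[1]], ">")) {
    body <- character(0)
    in_first <- FALSE
    for (ln in lines) {
      if (startsWith(ln, ">")) {
        if (in_first) break
        in_first <- TRUE
      } else if (in_first) {
        body <- c(body, ln)
      }
    }
    paste(body, collapse = "")
  } else {
    paste(lines[nzchar(lines)], collapse = "")
  }
}

#' Read a design from sequence files
#'
#' The scaffold file is FASTA (first record used) or a bare sequence.  The
#' staple file is either plain text with one 5'->3' staple sequence per line,
#' or a CSV with a `sequence` column (an `id` column, if present, is ignored:
#' ids are always assigned from row order).  Lowercase letters in staple
#' sequences mark non-hybridising subsequences.
#'
#' @param scaffold_path,staples_path File paths.
#' @param circular Scaffold circularity (default `TRUE`).
#' @param material Scaffold material.
#' @return An [design()] object.
#' @export
read_design <- function(scaffold_path, staples_path, circular = TRUE,
                        material = c("DNA", "RNA")) {
  material <- match.arg(material)
  sc <- scaffold(read_sequence_file(scaffold_path), circular, material)
  seqs <- read_staple_file(staples_path)
  staples <- lapply(seq_along(seqs), function(i) staple(seqs[[i]], id = i - 1L))
  design(sc, staples)
}

read_staple_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"sequence" %in% names(df)) {
      # headerless single/double column CSV: take the last column
      df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
      seqs <- as.character(df[[ncol(df)]])
    } else {
      seqs <- as.character(df$sequence)
    }
  } else {
    seqs <- trimws(lines)
  }
  blank <- !nzchar(seqs)
  if (any(blank)) {
    warning(sum(blank), " blank staple line(s) skipped")
    seqs <- seqs[!blank]
  }
  if (length(seqs) == 0L) stop("no staple sequences in ", path)
  seqs
}

#' Write a design back to text files
#'
#' Echo writer used for fixtures and round-trip checks: scaffold as
#' single-record FASTA, staples as one sequence per line with case markup
#' preserved byte-identically.
#'
#' @param design An [design()] object.
#' @param scaffold_path,staples_path Output paths.
#' @export
write_design <- function(design, scaffold_path, staples_path) {
  writeLines(c(">scaffold", design$scaffold$sequence), scaffold_path)
  writeLines(vapply(design$staples, function(s) s$sequence, character(1)),
             staples_path)
  invisible(design)
}

#' Split staples into virtual staples
#'
#' Each hybridising segment of a staple becomes one virtual staple; the
#' solver routes virtual staples independently and Stage 4 reassembles them.
#' Virtual staples are ordered by (parent id, segment index), so a design
#' with no markup yields one virtual staple per staple in input order.
#'
#' @param design An [design()] object.
#' @return List of virtual staples: `vid` (dense 0-based id), `parent_id`,
#'   `parent_segment_index` (0-based among hybridising segments),
#'   `offset` (staple base index of the segment start within the parent),
#'   `chars`, `length`.
#' @export
split_virtual <- function(design) {
  out <- list()
  vid <- 0L
  for (st in design$staples) {
    hyb <- st$segments[st$segments$kind == "hybridising", , drop = FALSE]
    for (k in seq_len(nrow(hyb))) {
      seg <- hyb[k, ]
      out[[length(out) + 1L]] <- list(
      vid = vid,
        parent_id = st$id,
        parent_segment_index = k - 1L,
        offset = seg$start,
        chars = st$chars[(seg$start + 1L):(seg$start + seg$length)],
        length = seg$length
      )
      vid <- vid + 1L
    }
  }
  out
}

# Given per-virtual-staple placements, produce per-parent placements with
# staple base indices in parent coordinates.  `placements` is a list parallel
# to `vstaples` whose elements are NULL (unplaced) or a sections matrix with
# columns start, mu, offset (offset relative to the virtual staple).
#
# Returns list(parent_routes = named list by parent id of sections matrices
# (offset in parent coordinates, plus segment index column), partial_parents,
# unplaced_parents, placed_parents).
merge_virtual <- function(vstaples, placements) {
  parent_ids <- unique(vapply(vstaples, function(v) v$parent_id, integer(1)))
  routes <- list()
  placed <- logical(length(parent_ids))
  partial <- logical(length(parent_ids))
  names(placed) <- names(partial) <- as.character(parent_ids)
  for (pid in parent_ids) {
    key <- as.character(pid)
    idx <- which(vapply(vstaples, function(v) v$parent_id == pid, logical(1)))
    segs <- list()
    n_placed <- 0L
    for (i in idx) {
      pl <- placements[[i]]
      if (is.null(pl)) next
      n_placed <- n_placed + 1L
      m <- pl
      m[, "offset"] <- m[, "offset"] + vstaples[[i]]$offset
      m <- cbind(m, segment = vstaples[[i]]$parent_segment_index)
      segs[[length(segs) + 1L]] <- m
    }
    if (n_placed > 0L) routes[[key]] <- do.call(rbind, segs)
    placed[key] <- n_placed == length(idx) && length(idx) > 0L
    partial[key] <- n_placed > 0L && n_placed < length(idx)
  }
  list(
    parent_routes = routes,
    placed_parents = as.integer(parent_ids[placed[as.character(parent_ids)]]),
    partial_parents = as.integer(parent_ids[partial[as.character(parent_ids)]]),
    unplaced_parents = as.integer(parent_ids[
      !placed[as.character(parent_ids)] & !partial[as.character(parent_ids)]])
  )
}

# Scaffold bases claimed by a section (start, mu): start, start-1, ...,
# start-(mu-1), i.e. the section runs toward scaffold 5' because staple and
# scaffold are antiparallel.  Modular for circular scaffolds.
section_bases <- function(start, mu, n, circular) {
  b <- start - 0:(mu - 1L)
  if (circular) b %% n else b
}
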