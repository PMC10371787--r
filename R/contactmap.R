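# Contact map data model, the base hamming distance d(g, r) between a ground
# truth and a recovered map, and the lossless conversion to/from the
# domain-level graph D.

#' Construct a contact map
#'
#' A contact map states, for every scaffold base, which staple base it is
#' hybridised to (staple id plus staple base index) or that it is unpaired.
#' It is a purely topological description of the folded origami and the
#' common currency between the solver, the ground-truth generator and the
#' layout stage.
#'
#' @param partner_staple Integer vector of length N: staple id pairing each
#'   scaffold base, `NA` for unpaired.
#' @param partner_base Integer vector of length N: the staple base index
#'   (0-based within the parent staple), `NA` for unpaired.
#' @param scaffold An [scaffold()] object (supplies N, circularity,
#'   material).
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(partner_staple, partner_base, scaffold) {
  stopifnot(inherits(scaffold, "origami_scaffold"))
  n <- scaffold$n
  partner_staple <- as.integer(partner_staple)
  partner_base <- as.integer(partner_base)
  if (length(partner_staple) != n || length(partner_base) != n) {
    stop("partner vectors must have scaffold length")
  }
  if (!identical(is.na(partner_staple), is.na(partner_base))) {
    stop("partner staple and base must be NA together")
  }
  keys <- paste(partner_staple, partner_base)[!is.na(partner_staple)]
  if (anyDuplicated(keys)) stop("a staple base may pair at most one scaffold base")
  structure(list(
    partner_staple = partner_staple,
    partner_base   = partner_base,
    n        = n,
    circular = scaffold$circular,
    material = scaffold$material
  ), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  paired <- sum(!is.na(x$partner_staple))
  cat(sprintf("<contact map> %d/%d scaffold bases paired, %d staples\n",
              paired, x$n, length(unique(stats::na.omit(x$partner_staple)))))
  invisible(x)
}

#' Base hamming distance between two contact maps
#'
#' The number of scaffold bases in `r` whose hybridisation partner must be
#' substituted to arrive at `g`: unpaired-vs-paired counts as a mismatch, and
#' partner equality requires the identical staple id *and* staple base index
#' (so junctions skewed by one base register).
#'
#' @param g,r Contact maps over the same scaffold.
#' @return Integer count.
#' @export
hamming <- function(g, r) {
  stopifnot(inherits(g, "contact_map"), inherits(r, "contact_map"))
  if (g$n != r$n) stop("contact maps cover scaffolds of different length")
  same <- (is.na(g$partner_staple) & is.na(r$partner_staple)) |
    (!is.na(g$partner_staple) & !is.na(r$partner_staple) &
       g$partner_staple == r$partner_staple &
       g$partner_base == r$partner_base)
  sum(!same)
}

#' Write / read a contact map as CSV
#'
#' Dialect: columns `scaffold_base,staple_id,staple_base` (0-based), unpaired
#' scaffold bases omitted.  Metadata (`n`, `circular`, `material`) travels in
#' `# key=value` header comments.
#'
#' @param cm A [contact_map()].
#' @param path Output path.
#' @export
write_contact_map <- function(cm, path) {
  hdr <- c(sprintf("# n=%d", cm$n),
           sprintf("# circular=%s", cm$circular),
           sprintf("# material=%s", cm$material),
           "scaffold_base,staple_id,staple_base")
  i <- which(!is.na(cm$partner_staple))
  rows <- sprintf("%d,%d,%d", i - 1L, cm$partner_staple[i], cm$partner_base[i])
  writeLines(c(hdr, rows), path)
  invisible(cm)
}

#' @rdname write_contact_map
#' @param scaffold Optional [scaffold()]; when omitted, a placeholder
#'   scaffold of the recorded length/topology is synthesised (poly-A), which
#'   is sufficient for purely topological operations.
#' @export
read_contact_map <- function(path, scaffold = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", meta), "="))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  n <- as.integer(meta[["n"]])
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (is.null(scaffold)) {
    scaffold <- scaffold(strrep("A", n),
                         circular = as.logical(meta[["circular"]]),
                         material = meta[["material"]])
  }
  ps <- rep(NA_integer_, n); pb <- rep(NA_integer_, n)
  ps[df$scaffold_base + 1L] <- df$staple_id
  pb[df$scaffold_base + 1L] <- df$staple_base
  contact_map(ps, pb, scaffold)
}

# ---------------------------------------------------------------------------
# Domain-level graph D
#
# Nodes sit at scaffold positions where domains start/finish (one node per
# boundary, identified by the scaffold base index that starts the following
# domain; a linear scaffold gains a terminal node "N" and dangle edges gain
# synthetic nodes).  Edges have five types: ss_scaffold, ds_scaffold,
# scaffold_nick, staple_crossover (or staple_loopout) and staple_dangle.  The
# graph is 1:1 with the contact map: ds/ss edges carry enough attributes to
# reconstruct it exactly.
# ---------------------------------------------------------------------------

# maximal runs of the contact map along the scaffold; returns data.frame
# start, len, ds (logical), staple, sb_start (staple base at run start)
scaffold_runs <- function(cm) {
  n <- cm$n
  ps <- cm$partner_staple; pb <- cm$partner_base
  # break before base b (0-based) if pairing does not continue from b-1
  brk <- logical(n)   # brk[b+1]: run boundary between b-1 and b
  for (b in seq_len(n) - 1L) {
    prev <- if (b == 0L) n - 1L else b - 1L
    if (b == 0L && !cm$circular) { brk[1L] <- TRUE; next }
    cont <- (is.na(ps[b + 1L]) && is.na(ps[prev + 1L])) ||
      (!is.na(ps[b + 1L]) && !is.na(ps[prev + 1L]) &&
         ps[b + 1L] == ps[prev + 1L] && pb[b + 1L] == pb[prev + 1L] - 1L)
    brk[b + 1L] <- !cont
  }
  if (!any(brk)) {
    # single run covering the whole circular scaffold
    starts <- 0L
    lens <- n
  } else {
    starts <- which(brk) - 1L
    k <- length(starts)
    nxt <- c(starts[-1L], if (cm$circular) starts[1L] + n else n)
    lens <- as.integer(nxt - starts)
  }
  data.frame(
    start = starts,
    len = lens,
    ds = !is.na(ps[starts + 1L]),
    staple = ps[starts + 1L],
    sb_start = pb[starts + 1L]
  )
}

#' Convert a contact map to the domain-level graph D
#'
#' @param cm A [contact_map()].
#' @param design Optional [design()]; when supplied, staple sequences are
#'   checked for consistency against the map and non-hybridising staple
#'   segments contribute `staple_dangle` edges and `staple_loopout` typing.
#' @return An object of class `domain_graph`: list with `nodes`
#'   (data.frame `id`, `pos`) and `edges` (data.frame `from`, `to`, `type`,
#'   `length`, `staple`, `sb_start`, `start`), plus scaffold metadata.
#' @export
to_domain_graph <- function(cm, design = NULL) {
  stopifnot(inherits(cm, "contact_map"))
  if (!is.null(design)) check_map_consistency(cm, design)
  n <- cm$n
  runs <- scaffold_runs(cm)
  node_after <- function(start, len) {
    e <- start + len
    if (cm$circular) e %% n else e
  }
  edges <- data.frame(
    from = as.character(runs$start),
    to = as.character(node_after(runs$start, runs$len)),
    type = ifelse(runs$ds, "ds_scaffold", "ss_scaffold"),
    length = runs$len,
    staple = runs$staple,
    sb_start = runs$sb_start,
    start = runs$start,
    stringsAsFactors = FALSE
  )
  if (!cm$circular) {
    edges <- rbind(edges, data.frame(
      from = as.character(n), to = "0", type = "scaffold_nick",
      length = 0L, staple = NA_integer_, sb_start = NA_integer_,
      start = NA_integer_, stringsAsFactors = FALSE))
  }

  # staple-level edges: crossovers / loop-outs between consecutive sections,
  # dangles at non-hybridising staple ends
  sec <- staple_sections_from_map(cm)
  for (sid in names(sec)) {
    s <- sec[[sid]]
    if (nrow(s) >= 2L) {
      for (k in seq_len(nrow(s) - 1L)) {
        gap <- s$sb_lo[k + 1L] - s$sb_hi[k] - 1L
        # node at section k's staple-3' boundary (low scaffold end of its run)
        from <- as.character(s$run_start[k])
        # node at section k+1's staple-5' boundary (just past its run)
        to <- as.character(node_after(s$run_start[k + 1L], s$len[k + 1L]))
        edges <- rbind(edges, data.frame(
          from = from, to = to,
          type = if (gap > 0L) "staple_loopout" else "staple_crossover",
          length = gap, staple = as.integer(sid), sb_start = NA_integer_,
          start = NA_integer_, stringsAsFactors = FALSE))
      }
    }
    if (!is.null(design)) {
      st <- design$staples[[as.integer(sid) + 1L]]
      lead <- s$sb_lo[1L]                      # unplaced staple bases at 5'
      trail <- st$length - 1L - s$sb_hi[nrow(s)]
      if (lead > 0L) {
        edges <- rbind(edges, data.frame(
          from = sprintf("d%s.5", sid),
          to = as.character(node_after(s$run_start[1L], s$len[1L])),
          type = "staple_dangle", length = lead, staple = as.integer(sid),
          sb_start = NA_integer_, start = NA_integer_, stringsAsFactors = FALSE))
      }
      if (trail > 0L) {
        edges <- rbind(edges, data.frame(
          from = as.character(s$run_start[nrow(s)]),
          to = sprintf("d%s.3", sid),
          type = "staple_dangle", length = trail, staple = as.integer(sid),
          sb_start = NA_integer_, start = NA_integer_, stringsAsFactors = FALSE))
      }
    }
  }
  ids <- unique(c(edges$from, edges$to))
  pos <- suppressWarnings(as.integer(ids))
  nodes <- data.frame(id = ids, pos = pos, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, n = n,
                 circular = cm$circular, material = cm$material),
            class = "domain_graph")
}

# per-staple placed sections, derived purely from the contact map: for each
# staple, maximal runs of consecutive staple bases whose scaffold positions
# step by -1.  Returns, per staple, data.frame(run_start, len, sb_lo, sb_hi)
# ordered by staple base.
staple_sections_from_map <- function(cm) {
  paired <- which(!is.na(cm$partner_staple)) - 1L
  out <- list()
  if (length(paired) == 0L) return(out)
  by_st <- split(paired, cm$partner_staple[paired + 1L])
  n <- cm$n
  for (sid in names(by_st)) {
    bases <- by_st[[sid]]
    sb <- cm$partner_base[bases + 1L]
    o <- order(sb)
    bases <- bases[o]; sb <- sb[o]
    # section break when staple base not consecutive or scaffold step != -1
    sb_ok <- sb[-1L] == sb[-length(sb)] + 1L
    sc_step <- if (cm$circular) {
      (bases[-length(bases)] - bases[-1L]) %% n == 1L
    } else {
      bases[-1L] == bases[-length(bases)] - 1L
    }
    step_ok <- c(FALSE, sb_ok & sc_step)
    grp <- cumsum(!step_ok)
    segs <- lapply(split(seq_along(bases), grp), function(ix) {
      data.frame(run_start = bases[ix[length(ix)]],   # lowest scaffold pos (staple-3' end)
                 len = length(ix),
                 sb_lo = sb[ix[1L]], sb_hi = sb[ix[length(ix)]])
    })
    out[[sid]] <- do.call(rbind, segs)
  }
  out
}

check_map_consistency <- function(cm, design) {
  sc <- design$scaffold
  i <- which(!is.na(cm$partner_staple))
  for (b in i) {
    sid <- cm$partner_staple[b]
    sb <- cm$partner_base[b]
    st <- design$staples[[sid + 1L]]
    if (sb >= st$length || st$chars[sb + 1L] != sc$req[b]) {
      stop(sprintf(
        "contact map inconsistent with sequences at scaffold base %d", b - 1L))
    }
  }
  invisible(TRUE)
}

#' Reconstruct a contact map from a domain-level graph
#'
#' Inverse of [to_domain_graph()]; the two functions are mutually inverse
#' (the 1:1 property of D).
#'
#' @param D A `domain_graph`.
#' @param scaffold Optional [scaffold()] for full metadata; a placeholder is
#'   synthesised when omitted.
#' @return A [contact_map()].
#' @export
from_domain_graph <- function(D, scaffold = NULL) {
  stopifnot(inherits(D, "domain_graph"))
  n <- D$n
  if (is.null(scaffold)) {
    scaffold <- scaffold(strrep("A", n), circular = D$circular,
                         material = D$material)
  }
  ps <- rep(NA_integer_, n); pb <- rep(NA_integer_, n)
  ds <- D$edges[D$edges$type == "ds_scaffold", , drop = FALSE]
  for (k in seq_len(nrow(ds))) {
    b <- if (D$circular) (ds$start[k] + 0:(ds$length[k] - 1L)) %% n
         else ds$start[k] + 0:(ds$length[k] - 1L)
    ps[b + 1L] <- ds$staple[k]
    pb[b + 1L] <- ds$sb_start[k] - 0:(ds$length[k] - 1L)
  }
  contact_map(ps, pb, scaffold)
}

#' @export
print.domain_graph <- function(x, ...) {
  tab <- table(x$edges$type)
  cat(sprintf("<domain graph> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Serialise a domain graph as node-link JSON
#'
#' @param D A `domain_graph`.
#' @param path Output path.
#' @export
write_domain_graph <- function(D, path) {
  jsonlite::write_json(list(
    meta = list(n = D$n, circular = D$circular, material = D$material),
    nodes = D$nodes, edges = D$edges), path,
    auto_unbox = TRUE, na = "null", digits = NA)
  invisible(D)
}

#' @rdname write_domain_graph
#' @export
read_domain_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- x$edges
  for (col in c("length", "staple", "sb_start", "start")) {
    edges[[col]] <- as.integer(edges[[col]])
  }
  nodes <- x$nodes
  nodes$pos <- as.integer(nodes$pos)
  structure(list(nodes = nodes, edges = edges, n = as.integer(x$meta$n),
                 circular = as.logical(x$meta$circular),
                 material = x$meta$material),
            class = "domain_graph")
}
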