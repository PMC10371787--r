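# Stage 0: staple routing trees (SRTs).
#
# An SRT node is a staple section (start: mu) -- the section's first staple
# base hybridises scaffold base `start` and the section runs mu bases toward
# scaffold 5' (staple and scaffold are antiparallel).  Root-to-leaf paths
# that consume the whole staple are the staple's candidate routes; partial
# routes are never kept.  The tree itself is represented by its complete
# route set (the only thing later stages consume), generated depth-first
# with sigma sibling pruning applied per sibling set.

#' Maximal antiparallel matches of a staple suffix on the scaffold
#'
#' Finds every scaffold position where the first `mu_min` or more bases of
#' the suffix pair antiparallel with the scaffold, each match extended
#' greedily until mismatch or staple end (maximal runs only; no sub-maximal
#' split points are generated -- this is the source of the solver's
#' characteristic "overshoot" behaviour at junctions).
#'
#' @param suffix_chars Character vector: remaining staple bases, 5'->3'.
#' @param sc An [scaffold()] object.
#' @param mu_min Minimum section length (bases).
#' @return data.frame with 0-based `start` and `mu`.
#' @export
maximal_matches <- function(suffix_chars, sc, mu_min) {
  L <- length(suffix_chars)
  empty <- data.frame(start = integer(0), mu = integer(0))
  if (L < mu_min || L == 0L) return(empty)
  starts <- which(sc$req == suffix_chars[1L]) - 1L
  if (length(starts) == 0L) return(empty)
  n <- sc$n
  mus <- integer(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    mu <- 1L
    while (mu < L) {
      b <- s - mu
      if (b < 0L) {
        if (!sc$circular) break
        b <- b + n
      }
      if (sc$req[b + 1L] == suffix_chars[mu + 1L]) mu <- mu + 1L else break
    }
    mus[i] <- mu
  }
  keep <- mus >= mu_min
  data.frame(start = starts[keep], mu = mus[keep])
}

#' Build the staple routing tree for one (virtual) staple
#'
#' Depth-first expansion: children of a node are the maximal matches of the
#' remaining staple suffix anywhere on the scaffold; within each sibling
#' set, only siblings with `mu >= max(mu) - sigma` are kept; recursion stops
#' when the staple is fully consumed (a complete route) or no children exist
#' (dead branch, discarded).  Sections of one route may not claim a shared
#' scaffold base (self-overlap is physically impossible; adjacency is
#' allowed).  If the tree exceeds `max_nodes` nodes the staple is aborted
#' with an empty SRT and flagged, so that pathologically repetitive inputs
#' degrade gracefully.
#'
#' @param vstaple A virtual staple (element of [split_virtual()]).
#' @param sc An [scaffold()] object.
#' @param mu_min,sigma Solver parameters (bases).
#' @param max_nodes Tree-size guard (default 1e6 nodes).
#' @return Object of class `srt`: list with `vid`, `routes` (list; each a
#'   list with `sections` matrix (`start`, `mu`, `offset`) and `bases`
#'   (claimed scaffold bases in staple order)), `aborted`.
#' @export
build_srt <- function(vstaple, sc, mu_min, sigma, max_nodes = 1e6) {
  L <- vstaple$length
  chars <- vstaple$chars
  env <- new.env(parent = emptyenv())
  env$routes <- vector("list", 8L)
  env$nr <- 0L
  env$nodes <- 0L
  env$aborted <- FALSE

  rec <- function(offset, claimed, sections) {
    if (env$aborted) return(invisible())
    if (offset == L) {
      env$nr <- env$nr + 1L
      if (env$nr > length(env$routes)) {
        env$routes <- c(env$routes, vector("list", length(env$routes)))
      }
      m <- do.call(rbind, sections)
      env$routes[[env$nr]] <- list(sections = m, bases = claimed)
      return(invisible())
    }
    mm <- maximal_matches(chars[(offset + 1L):L], sc, mu_min)
    if (nrow(mm) == 0L) return(invisible())
    mm <- mm[mm$mu >= max(mm$mu) - sigma, , drop = FALSE]
    mm <- mm[order(mm$start), , drop = FALSE]
    for (i in seq_len(nrow(mm))) {
      env$nodes <- env$nodes + 1L
      if (env$nodes > max_nodes) {
        env$aborted <- TRUE
        return(invisible())
      }
      b <- section_bases(mm$start[i], mm$mu[i], sc$n, sc$circular)
      if (!sc$circular && any(b < 0L)) next
      if (any(b %in% claimed)) next           # self-overlap rejected
      rec(offset + mm$mu[i], c(claimed, b),
          c(sections, list(c(start = mm$start[i], mu = mm$mu[i],
                             offset = offset))))
    }
    invisible()
  }
  rec(0L, integer(0), list())
  routes <- if (env$aborted) list() else env$routes[seq_len(env$nr)]
  structure(list(vid = vstaple$vid, length = L, routes = routes,
                 aborted = env$aborted), class = "srt")
}

#' @export
print.srt <- function(x, ...) {
  cat(sprintf("<srt staple %d> %d route(s)%s\n", x$vid, length(x$routes),
              if (x$aborted) " [aborted: tree-size guard]" else ""))
  invisible(x)
}

#' Footprint of an SRT
#'
#' The set of scaffold bases that *all* surviving routes pass through: the
#' bases the staple definitely claims.  Maximal (the whole route) when one
#' route survives; often empty while many routes compete.
#'
#' @param routes List of routes (as stored in an `srt`), or an `srt`.
#' @return Sorted integer vector of 0-based scaffold bases.
#' @export
footprint <- function(routes) {
  if (inherits(routes, "srt")) routes <- routes$routes
  if (length(routes) == 0L) return(integer(0))
  fp <- routes[[1L]]$bases
  for (r in routes[-1L]) {
    fp <- intersect(fp, r$bases)
    if (length(fp) == 0L) break
  }
  sort(fp)
}

#' Route statistics over a set of SRTs
#'
#' @param srts List of `srt` objects.
#' @return List: `n_staples`, `n_zero_route`, `n_one_route`,
#'   `n_multi_route`, `mean_routes_multi`, `max_routes`, `n_aborted`.
#' @export
route_stats <- function(srts) {
  nr <- vapply(srts, function(s) length(s$routes), integer(1))
  multi <- nr[nr > 1L]
  list(
    n_staples = length(srts),
    n_zero_route = sum(nr == 0L),
    n_one_route = sum(nr == 1L),
    n_multi_route = length(multi),
    mean_routes_multi = if (length(multi)) mean(multi) else 0,
    max_routes = if (length(nr)) max(nr) else 0L,
    n_aborted = sum(vapply(srts, function(s) s$aborted, logical(1)))
  )
}

#' Dump an SRT route set as indented text
#'
#' Sections are printed in the (start_base: length) notation used by the
#' solver's reports.
#'
#' @param srt An `srt`.
#' @return Character vector of lines.
#' @export
format_srt <- function(srt) {
  if (length(srt$routes) == 0L) {
    return(sprintf("staple %d: no complete routes%s", srt$vid,
                   if (srt$aborted) " (aborted)" else ""))
  }
  c(sprintf("staple %d: %d route(s)", srt$vid, length(srt$routes)),
    unlist(lapply(seq_along(srt$routes), function(i) {
      s <- srt$routes[[i]]$sections
      sprintf("  route %d: %s", i,
              paste(sprintf("(%d: %d)", s[, "start"], s[, "mu"]),
                    collapse = " -> "))
    })))
}
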