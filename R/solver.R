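# Stages 1-4 of the contact-map solver: footprint constraint propagation,
# clearest-shortest-path placement of residual multi-route staples, overlap
# repair by overshoot trimming, and virtual-staple reassembly.  Plus the
# NAIVE single-pass baseline.
#
# Solver state is a plain environment over *virtual* staples:
#   routes[[i]]  surviving routes of staple i (list; length 1 == placed)
#   fp[[i]]      current footprint (0-based scaffold bases)
#   counts       integer vector over scaffold bases: number of staples whose
#                footprint claims the base
#   dead[i]      staple became unplaceable (SRT emptied / aborted / no route)

#' Solver parameters
#'
#' @param mu_min Minimum staple section length (bases).  Typical 5-6.
#' @param sigma Sibling competition window (bases): within each sibling set
#'   of a routing tree, matches shorter than the best sibling by more than
#'   `sigma` are discarded.  Typical 0-10.
#' @param beta Overlap tolerance in (0, 1]: a section is unavailable to a
#'   route if at least a `beta` fraction of its scaffold bases is already
#'   claimed by other staples' footprints.
#' @param mode `"deterministic"` (staples polled in input order, the
#'   default) or `"nondeterministic"` (fresh seeded shuffle every sweep).
#' @param seed Integer seed used by non-deterministic polling.
#' @param max_nodes Routing-tree size guard per staple.
#' @return List of class `solver_params`.  Defaults are the raster consensus
#'   (6, 4, 0.3); see [preset_params()] for the wireframe preset.
#' @export
solver_params <- function(mu_min = 6L, sigma = 4L, beta = 0.3,
                          mode = c("deterministic", "nondeterministic"),
                          seed = 1L, max_nodes = 1e6) {
  mode <- match.arg(mode)
  stopifnot(mu_min >= 1, sigma >= 0, beta > 0, beta <= 1)
  structure(list(mu_min = as.integer(mu_min), sigma = as.integer(sigma),
                 beta = beta, mode = mode, seed = as.integer(seed),
                 max_nodes = max_nodes),
            class = "solver_params")
}

#' Consensus parameter presets
#'
#' @param type `"raster"` (mu_min 6, sigma 4, beta 0.3) or `"wireframe"`
#'   (mu_min 5, sigma 2, beta 0.25).
#' @param ... Overrides passed to [solver_params()].
#' @export
preset_params <- function(type = c("raster", "wireframe"), ...) {
  type <- match.arg(type)
  defaults <- if (type == "raster") {
    list(mu_min = 6L, sigma = 4L, beta = 0.3)
  } else {
    list(mu_min = 5L, sigma = 2L, beta = 0.25)
  }
  do.call(solver_params, utils::modifyList(defaults, list(...)))
}

solver_error <- function(code, message) {
  stop(structure(class = c(paste0("revnano_", tolower(code)),
                           "revnano_error", "error", "condition"),
                 list(message = sprintf("[%s] %s", code, message),
                      call = NULL, code = code)))
}

new_state <- function(srts, n) {
  st <- new.env(parent = emptyenv())
  st$n <- n
  st$routes <- lapply(srts, function(s) s$routes)
  st$dead <- vapply(srts, function(s) length(s$routes) == 0L, logical(1))
  st$fp <- lapply(st$routes, footprint)
  st$counts <- integer(n)
  for (fp in st$fp) st$counts[fp + 1L] <- st$counts[fp + 1L] + 1L
  st
}

n_routes <- function(st) vapply(st$routes, length, integer(1))

# enlarge staple i's footprint to `new_fp` (must be a superset of the old)
update_footprint <- function(st, i, new_fp) {
  add <- setdiff(new_fp, st$fp[[i]])
  if (length(add)) st$counts[add + 1L] <- st$counts[add + 1L] + 1L
  st$fp[[i]] <- new_fp
}

drop_staple <- function(st, i) {
  old <- st$fp[[i]]
  if (length(old)) st$counts[old + 1L] <- st$counts[old + 1L] - 1L
  st$fp[[i]] <- integer(0)
  st$routes[[i]] <- list()
  st$dead[i] <- TRUE
}

#' Stage 1: footprint constraint propagation
#'
#' Repeated sweeps poll every staple (input order in deterministic mode; a
#' fresh seeded shuffle per sweep otherwise).  A polled staple prunes every
#' route containing a section at least a `beta` fraction of whose scaffold
#' bases is already claimed by *other* staples' footprints, then recasts its
#' (never-shrinking) footprint.  Sweeps stop when a full sweep enlarges no
#' footprint.  A staple whose route set empties is marked unplaceable and
#' withdrawn, not fatal.
#'
#' @param st Solver state (internal; see [solve_design()]).
#' @param params A [solver_params()].
#' @param sc The [scaffold()].
#' @return Number of sweeps run (state is modified in place).
#' @keywords internal
stage1_propagate <- function(st, params, sc) {
  n <- st$n
  sweeps <- 0L
  if (params$mode == "nondeterministic") set.seed(params$seed)
  repeat {
    sweeps <- sweeps + 1L
    order_ <- seq_along(st$routes)
    if (params$mode == "nondeterministic") order_ <- sample(order_)
    enlarged <- FALSE
    for (i in order_) {
      if (st$dead[i] || length(st$routes[[i]]) <= 1L) next
      others <- st$counts
      own <- st$fp[[i]]
      if (length(own)) others[own + 1L] <- others[own + 1L] - 1L
      keep <- vapply(st$routes[[i]], function(r) {
        s <- r$sections
        for (k in seq_len(nrow(s))) {
          b <- section_bases(s[k, "start"], s[k, "mu"], n, sc$circular)
          if (sum(others[b + 1L] > 0L) / s[k, "mu"] >= params$beta) {
            return(FALSE)
          }
        }
        TRUE
      }, logical(1))
      if (all(keep)) next
      st$routes[[i]] <- st$routes[[i]][keep]
      if (length(st$routes[[i]]) == 0L) {
        drop_staple(st, i)
        next
      }
      new_fp <- footprint(st$routes[[i]])
      if (length(new_fp) > length(st$fp[[i]])) {
        update_footprint(st, i, new_fp)
        enlarged <- TRUE
      }
    }
    if (!enlarged) break
  }
  sweeps
}

#' Stage 2 entry check
#'
#' The clearest-shortest-path heuristic needs a well-connected scaffold base
#' graph, so the solver refuses to continue (error `E2`) when fewer than
#' 65 % of (virtual) staples are placed after Stage 1.  The threshold is
#' fixed, independent of the solver parameters.
#'
#' @param n_placed,n_total Placed and total virtual staple counts.
#' @return Invisibly `TRUE`, or signals a condition of class `revnano_e2`.
#' @export
stage2_check <- function(n_placed, n_total) {
  if (n_total > 0L && n_placed / n_total < 0.65) {
    solver_error("E2", sprintf(
      "only %d/%d staples (%.1f%%) placed in Stage 1; not enough for reliable shortest-path calculations",
      n_placed, n_total, 100 * n_placed / n_total))
  }
  invisible(TRUE)
}

# Scaffold base graph B: one vertex per scaffold base; edges are backbone
# adjacencies plus one edge per placed-staple crossover (linking the base
# paired to the last base of one section to the base paired to the first
# base of the next).  Built only from placed (single-route) staples.
build_base_graph <- function(st, sc) {
  n <- st$n
  ev <- c(rbind(0:(n - 2L), 1:(n - 1L)))
  if (sc$circular) ev <- c(ev, n - 1L, 0L)
  for (i in seq_along(st$routes)) {
    if (length(st$routes[[i]]) != 1L) next
    s <- st$routes[[i]][[1L]]$sections
    if (nrow(s) < 2L) next
    for (k in seq_len(nrow(s) - 1L)) {
      a <- s[k, "start"] - s[k, "mu"] + 1L
      b <- s[k + 1L, "start"]
      if (sc$circular) a <- a %% n
      ev <- c(ev, a, b)
    }
  }
  igraph::make_graph(ev + 1L, n = n, directed = FALSE)
}

route_endpoints <- function(route, n, circular) {
  s <- route$sections
  e5 <- s[1L, "start"]
  e3 <- s[nrow(s), "start"] - s[nrow(s), "mu"] + 1L
  if (circular) e3 <- e3 %% n
  c(e5, e3)
}

#' Stage 2: clearest-shortest-path placement
#'
#' Each remaining multi-route ("G1") staple values every route by the
#' shortest-path length (edge count) through the scaffold base graph B
#' between the scaffold bases paired to the staple's 5' and 3' ends.  The
#' staple with the greatest margin between its best and next-best route
#' value -- the clearest shortest path -- is forced to its best route (ties
#' broken toward the highest staple id), the Stage-1 propagation is re-run
#' to absorb the ripple cascade, B is rebuilt, and the cycle repeats until
#' no G1 staple remains or none has a finite best route.  Staples still
#' multi-route at the end are omitted from the contact map.
#'
#' @inheritParams stage1_propagate
#' @return List with `iterations` and `forced` (vids forced in order).
#' @keywords internal
stage2_place <- function(st, params, sc) {
  iterations <- 0L
  forced <- integer(0)
  repeat {
    g1 <- which(n_routes(st) >= 2L)
    if (length(g1) == 0L) break
    B <- build_base_graph(st, sc)
    best_route <- integer(length(g1))
    margin <- rep(-Inf, length(g1))
    best_val <- rep(Inf, length(g1))
    for (gi in seq_along(g1)) {
      i <- g1[gi]
      eps <- t(vapply(st$routes[[i]], route_endpoints, integer(2),
                      n = st$n, circular = sc$circular))
      vals <- vapply(seq_len(nrow(eps)), function(k) {
        igraph::distances(B, v = eps[k, 1L] + 1L, to = eps[k, 2L] + 1L)[1, 1]
      }, numeric(1))
      o <- order(vals)
      best_val[gi] <- vals[o[1L]]
      best_route[gi] <- o[1L]
      margin[gi] <- vals[o[2L]] - vals[o[1L]]
    }
    selectable <- is.finite(best_val)
    if (!any(selectable)) break
    m <- max(margin[selectable])
    cand <- g1[selectable & margin == m]
    i <- cand[which.max(cand)]          # highest id wins ties
    gi <- match(i, g1)
    st$routes[[i]] <- st$routes[[i]][best_route[gi]]
    update_footprint(st, i, sort(st$routes[[i]][[1L]]$bases))
    forced <- c(forced, i - 1L)
    iterations <- iterations + 1L
    stage1_propagate(st, params, sc)
  }
  list(iterations = iterations, forced = forced)
}

#' Stage 3: repair staple-staple overlaps
#'
#' Overlaps left by the fuzzy (`beta`-tolerant) placement stages are
#' remedied as section overshoots: where two placed sections share scaffold
#' bases, the section whose staple-3' terminus intrudes into the other
#' section is trimmed back (greedy sequence matching can only overrun a
#' designed junction in the staple 5'->3' direction, which extends a
#' section's 3' terminus).  Trimmed staple bases become unpaired.  A base
#' claimed by three or more staples, an overlap with no terminus-only
#' resolution, or a trim that would erase a whole section raises error `E4`.
#'
#' @param placements Named list (by staple key) of sections matrices with
#'   columns `start`, `mu`, `offset`.
#' @param sc The [scaffold()].
#' @return List with `placements` (trimmed) and `trims` (data.frame).
#' @export
stage3_fix_overlaps <- function(placements, sc) {
  n <- sc$n
  trims <- list()
  keys <- names(placements)
  repeat {
    cl <- do.call(rbind, lapply(keys, function(key) {
      s <- placements[[key]]
      do.call(rbind, lapply(seq_len(nrow(s)), function(k) {
        data.frame(
          base = section_bases(s[k, "start"], s[k, "mu"], n, sc$circular),
          key = key, sec = k, stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(cl)) break
    n_claims <- table(cl$base)
    if (any(n_claims >= 3L)) {
      solver_error("E4", sprintf(
        "unresolvable 3-staple overlap at scaffold base %s",
        names(n_claims)[n_claims >= 3L][1L]))
    }
    ov <- as.integer(names(n_claims)[n_claims == 2L])
    if (length(ov) == 0L) break
    two <- cl[cl$base == ov[1L], ]
    keyA <- two$key[1L]; secA <- two$sec[1L]
    keyB <- two$key[2L]; secB <- two$sec[2L]
    sA <- placements[[keyA]][secA, ]
    sB <- placements[[keyB]][secB, ]
    basesA <- section_bases(sA[["start"]], sA[["mu"]], n, sc$circular)
    basesB <- section_bases(sB[["start"]], sB[["mu"]], n, sc$circular)
    O <- intersect(basesA, basesB)
    k <- length(O)
    tailA <- basesA[(length(basesA) - k + 1L):length(basesA)]
    tailB <- basesB[(length(basesB) - k + 1L):length(basesB)]
    a_terminal <- setequal(O, tailA)
    b_terminal <- setequal(O, tailB)
    victim <- if (a_terminal && b_terminal) {
      # head-on collision: the higher staple id yields
      if (as.integer(keyA) >= as.integer(keyB)) "A" else "B"
    } else if (a_terminal) "A" else if (b_terminal) "B" else {
      solver_error("E4", sprintf(
        "overlap of staples %s/%s at scaffold base %d has no terminus-only resolution",
        keyA, keyB, O[1L]))
    }
    vkey <- if (victim == "A") keyA else keyB
    vsec <- if (victim == "A") secA else secB
    vmu <- placements[[vkey]][vsec, "mu"]
    if (vmu - k < 1L) {
      solver_error("E4", sprintf(
        "trimming staple %s section %d by %d bases would erase it", vkey,
        vsec, k))
    }
    placements[[vkey]][vsec, "mu"] <- vmu - k
    trims[[length(trims) + 1L]] <- data.frame(
      staple = vkey, section = vsec, trimmed = k, stringsAsFactors = FALSE)
  }
  list(placements = placements,
       trims = if (length(trims)) do.call(rbind, trims) else
         data.frame(staple = character(0), section = integer(0),
                    trimmed = integer(0)))
}

# assemble the parent-level contact map from merged parent routes
map_from_parent_routes <- function(parent_routes, sc) {
  ps <- rep(NA_integer_, sc$n)
  pb <- rep(NA_integer_, sc$n)
  for (key in names(parent_routes)) {
    sid <- as.integer(key)
    s <- parent_routes[[key]]
    for (k in seq_len(nrow(s))) {
      b <- section_bases(s[k, "start"], s[k, "mu"], sc$n, sc$circular)
      if (any(!is.na(ps[b + 1L]))) {
        solver_error("E4", "residual overlapping claims after Stage 3")
      }
      ps[b + 1L] <- sid
      pb[b + 1L] <- s[k, "offset"] + 0:(s[k, "mu"] - 1L)
    }
  }
  contact_map(ps, pb, sc)
}

#' Solve a design: recover the contact map from sequences
#'
#' Runs the full constraint-programming pipeline: virtual-staple splitting,
#' routing-tree construction (Stage 0, placing definite single-route
#' staples), footprint propagation (Stage 1), the `E2` coverage check,
#' clearest-shortest-path placement (Stage 2), overlap repair (Stage 3) and
#' virtual-staple reassembly (Stage 4).
#'
#' @param design An [design()] object.
#' @param params A [solver_params()].
#' @return Object of class `revnano_result`: list with `contact_map` and
#'   `report` (per-stage staple counts, SP%, omitted staple ids, iteration
#'   counts, trims, parameters).
#' @export
solve_design <- function(design, params = solver_params()) {
  sc <- design$scaffold
  t0 <- Sys.time()
  vst <- split_virtual(design)
  if (length(vst) == 0L) {
    report <- list(n_virtual = 0L, sp_percent = 100,
                   note = "empty staple list; SP% reported as 100 by convention")
    return(structure(list(
      contact_map = contact_map(rep(NA_integer_, sc$n),
                                rep(NA_integer_, sc$n), sc),
      report = report), class = "revnano_result"))
  }
  srts <- lapply(vst, build_srt, sc = sc, mu_min = params$mu_min,
                 sigma = params$sigma, max_nodes = params$max_nodes)
  stats0 <- route_stats(srts)
  st <- new_state(srts, sc$n)
  placed_stage0 <- sum(n_routes(st) == 1L)
  sweeps <- stage1_propagate(st, params, sc)
  placed_stage1 <- sum(n_routes(st) == 1L)
  stage2_check(placed_stage1, length(vst))
  s2 <- stage2_place(st, params, sc)
  placed_stage2 <- sum(n_routes(st) == 1L)
  omitted_vids <- which(n_routes(st) >= 2L) - 1L

  placements <- stats::setNames(
    lapply(seq_along(vst), function(i) {
      if (length(st$routes[[i]]) == 1L) st$routes[[i]][[1L]]$sections else NULL
    }), as.character(seq_along(vst) - 1L))
  placed_keys <- names(placements)[!vapply(placements, is.null, logical(1))]
  s3 <- stage3_fix_overlaps(placements[placed_keys], sc)
  for (key in placed_keys) placements[[key]] <- s3$placements[[key]]

  merged <- merge_virtual(vst, placements)
  cm <- map_from_parent_routes(merged$parent_routes, sc)
  n_parents <- length(design$staples)
  sp <- if (n_parents == 0L) 100 else
    100 * length(merged$placed_parents) / n_parents
  report <- list(
    params = unclass(params)[c("mu_min", "sigma", "beta", "mode", "seed")],
    n_virtual = length(vst),
    n_parents = n_parents,
    stage0 = stats0,
    placed_stage0 = placed_stage0,
    stage1_sweeps = sweeps,
    placed_stage1 = placed_stage1,
    stage2_iterations = s2$iterations,
    stage2_forced = s2$forced,
    placed_stage2 = placed_stage2,
    omitted_virtual = omitted_vids,
    unplaceable_virtual = which(st$dead) - 1L,
    trims = s3$trims,
    partial_parents = merged$partial_parents,
    unplaced_parents = merged$unplaced_parents,
    sp_percent = sp,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (length(merged$partial_parents)) {
    message("partially placed parent staple(s): ",
            paste(merged$partial_parents, collapse = ","))
  }
  structure(list(contact_map = cm, report = report),
            class = "revnano_result")
}

#' @export
print.revnano_result <- function(x, ...) {
  r <- x$report
  cat("<solver result>\n")
  if (!is.null(r$note)) cat(" ", r$note, "\n")
  if (!is.null(r$stage0)) {
    cat(sprintf("  stage 0: %d/%d single-route (%d multi, %d zero)\n",
                r$stage0$n_one_route, r$n_virtual, r$stage0$n_multi_route,
                r$stage0$n_zero_route))
    cat(sprintf("  stage 1: %d placed after %d sweep(s)\n",
                r$placed_stage1, r$stage1_sweeps))
    cat(sprintf("  stage 2: %d placed after %d forced placement(s)\n",
                r$placed_stage2, r$stage2_iterations))
    cat(sprintf("  stage 3: %d trim(s); omitted: %d\n",
                nrow(r$trims), length(r$omitted_virtual)))
  }
  cat(sprintf("  SP%% = %.1f\n", r$sp_percent))
  invisible(x)
}

#' NAIVE baseline solver
#'
#' Places each staple in isolation: repeatedly find all maximal antiparallel
#' complementary matches (of at least `mu_min` bases) of the remaining
#' staple prefix anywhere on the scaffold, commit the longest (ties broken
#' toward the lowest scaffold start index), truncate, and repeat.  A staple
#' whose remainder finds no match is left entirely unplaced.  Overlap repair
#' and virtual-staple reassembly then run as in the full solver.  Works on
#' repeat-free scaffolds; fails when a repeated scaffold region replicates a
#' staple binding site.
#'
#' @param design An [design()] object.
#' @param mu_min Minimum match length (bases).
#' @return A `revnano_result`.
#' @export
solve_naive <- function(design, mu_min = 6L) {
  sc <- design$scaffold
  vst <- split_virtual(design)
  placements <- stats::setNames(vector("list", length(vst)),
                                as.character(seq_along(vst) - 1L))
  for (i in seq_along(vst)) {
    v <- vst[[i]]
    offset <- 0L
    secs <- list()
    ok <- TRUE
    while (offset < v$length) {
      mm <- maximal_matches(v$chars[(offset + 1L):v$length], sc, mu_min)
      if (nrow(mm) == 0L) { ok <- FALSE; break }
      mm <- mm[order(-mm$mu, mm$start), , drop = FALSE]
      secs[[length(secs) + 1L]] <- c(start = mm$start[1L], mu = mm$mu[1L],
                                     offset = offset)
      offset <- offset + mm$mu[1L]
    }
    if (ok) placements[[i]] <- do.call(rbind, secs)
  }
  placed_keys <- names(placements)[!vapply(placements, is.null, logical(1))]
  s3 <- stage3_fix_overlaps(placements[placed_keys], sc)
  for (key in placed_keys) placements[[key]] <- s3$placements[[key]]
  merged <- merge_virtual(vst, placements)
  cm <- map_from_parent_routes(merged$parent_routes, sc)
  n_parents <- length(design$staples)
  sp <- if (n_parents == 0L) 100 else
    100 * length(merged$placed_parents) / n_parents
  structure(list(contact_map = cm, report = list(
    solver = "naive", params = list(mu_min = mu_min),
    n_virtual = length(vst),
    unplaced_virtual = which(vapply(placements, is.null, logical(1))) - 1L,
    trims = s3$trims,
    partial_parents = merged$partial_parents,
    unplaced_parents = merged$unplaced_parents,
    sp_percent = sp)), class = "revnano_result")
}
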