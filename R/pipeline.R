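# Pipeline orchestration: solve -> domain graph -> junction ambiguity ->
# embedding -> HTML export, with a JSON run report; and the parameter scan
# used to chart solver sensitivity.

#' Run the full reverse-engineering pipeline
#'
#' Executes [solve_design()], [to_domain_graph()], [ambig_all()],
#' [embed_domain_graph()] / [refine_layout()] and [export_html()] for the
#' requested views, writing every artifact into `out_dir` with a provenance
#' header (solver parameters, seed, SP%, and the base hamming distance when
#' a ground-truth contact map is supplied).
#'
#' @param design An [design()] object.
#' @param out_dir Output directory (created if needed).
#' @param params A [solver_params()].
#' @param dim Layout dimension, 2 or 3.
#' @param layout_seed Seed for the embedding.
#' @param refine_iterations Force-refinement iterations (0 disables).
#' @param views Character subset of `c("staples", "scaffold", "ambiguity")`.
#' @param truth Optional ground-truth [contact_map()].
#' @param solver `"revnano"` (default) or `"naive"`.
#' @return Invisibly, a list with `result`, `domain_graph`, `ambig`,
#'   `coords`, `report_path` and the artifact paths.
#' @export
run_pipeline <- function(design, out_dir, params = solver_params(),
                         dim = 2L, layout_seed = 1L,
                         refine_iterations = 25L,
                         views = c("staples", "scaffold", "ambiguity"),
                         truth = NULL, solver = c("revnano", "naive")) {
  solver <- match.arg(solver)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- if (solver == "revnano") solve_design(design, params)
         else solve_naive(design, params$mu_min)
  cm <- res$contact_map
  D <- to_domain_graph(cm, design)
  amb <- ambig_all(cm, design)
  coords <- embed_domain_graph(D, dim = dim, seed = layout_seed)
  stress0 <- attr(coords, "stress_initial")
  stress_embed <- layout_stress(coords, D)
  if (refine_iterations > 0L) {
    coords2 <- refine_layout(coords, D, iterations = refine_iterations,
                             seed = layout_seed)
    attr(coords2, "stress_initial") <- stress0
    coords <- coords2
  }
  schem <- guide_schematic(D, coords, design, cm, ambig = amb,
                           report = res$report)

  paths <- list(
    contact_map = file.path(out_dir, "contact_map.csv"),
    domain_graph = file.path(out_dir, "domain_graph.json"),
    junctions = file.path(out_dir, "junctions.csv"),
    coordinates = file.path(out_dir, "coordinates.csv"),
    report = file.path(out_dir, "report.json")
  )
  write_contact_map(cm, paths$contact_map)
  write_domain_graph(D, paths$domain_graph)
  write_junction_report(amb, paths$junctions)
  write_coordinates(coords, paths$coordinates)
  for (v in views) {
    p <- file.path(out_dir, sprintf("schematic_%s.html", v))
    export_html(schem, v, p)
    paths[[paste0("schematic_", v)]] <- p
  }
  report <- res$report
  report$solver <- solver
  report$layout <- list(dim = dim, seed = layout_seed,
                        refine_iterations = refine_iterations,
                        stress_initial = stress0,
                        stress_embed = stress_embed,
                        stress_final = layout_stress(coords, D))
  report$n_junctions <- amb$n_junctions
  report$n_ambiguous_junctions <- amb$n_ambiguous
  report$i2_zero <- amb$i2_zero
  if (!is.null(truth)) report$hamming <- hamming(truth, cm)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(list(result = res, domain_graph = D, ambig = amb,
                 coords = coords, paths = paths, report = report))
}

#' Scan solver parameter space
#'
#' Runs the solver at every point of a `(mu_min, sigma, beta)` grid,
#' recording staples placed (SP%), the hamming distance to ground truth
#' when supplied, and the error code (`E2`/`E4`) at points where the solver
#' terminates with an error -- error points are recorded, never fatal, so
#' the scan output is directly heatmappable.
#'
#' @param design An [design()] object.
#' @param grid data.frame with columns `mu_min`, `sigma`, `beta` (one row
#'   per parameter point).
#' @param truth Optional ground-truth [contact_map()].
#' @param ... Further arguments to [solver_params()] (mode, seed, ...).
#' @return data.frame: the grid plus `sp_percent`, `hamming`, `error`.
#' @export
param_scan <- function(design, grid, truth = NULL, ...) {
  stopifnot(nrow(grid) > 0, all(c("mu_min", "sigma", "beta") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- solver_params(mu_min = grid$mu_min[i], sigma = grid$sigma[i],
                       beta = grid$beta[i], ...)
    out <- data.frame(mu_min = p$mu_min, sigma = p$sigma, beta = p$beta,
                      sp_percent = NA_real_, hamming = NA_integer_,
                      error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch(solve_design(design, p), revnano_error = function(e) e)
    if (inherits(res, "revnano_error")) {
      out$error <- res$code
    } else {
      out$sp_percent <- res$report$sp_percent
      if (!is.null(truth)) out$hamming <- hamming(truth, res$contact_map)
    }
    out
  })
  do.call(rbind, rows)
}
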