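# Stage two of the pipeline: embed the domain-level graph in 2D/3D by
# stress minimisation against graph-theoretic distances, optionally refine
# with weak repulsive forces, and export interactive HTML guide schematics.

# Edge weights approximate physical lengths: scaffold domain and dangle
# edges weigh their base count (min 1); crossover, loop-out and nick edges
# weigh 1, so helices render with proportional lengths.
domain_igraph <- function(D) {
  w <- ifelse(D$edges$type %in% c("ds_scaffold", "ss_scaffold", "staple_dangle"),
              pmax(D$edges$length, 1L), 1L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = D$edges$from, to = D$edges$to, weight = w,
               type = D$edges$type, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = D$nodes$id, stringsAsFactors = FALSE))
  g
}

circular_start <- function(g, dim, seed) {
  nv <- igraph::vcount(g)
  theta <- 2 * pi * (seq_len(nv) - 1L) / nv
  r <- nv / (2 * pi)
  coords <- cbind(r * cos(theta), r * sin(theta))
  if (dim == 3L) {
    set.seed(seed)
    coords <- cbind(coords, stats::rnorm(nv, sd = r / 20))
  }
  rownames(coords) <- igraph::V(g)$name
  coords
}

#' Normalised stress of a layout
#'
#' `sum w_ij (|x_i - x_j| - d_ij)^2` over node pairs with `w_ij = 1/d_ij^2`,
#' where `d_ij` are weighted shortest-path distances -- the quantity the
#' spring embedder minimises.
#'
#' @param coords Coordinate matrix (rows named by node id).
#' @param D A `domain_graph`.
#' @return Numeric scalar.
#' @export
layout_stress <- function(coords, D) {
  g <- domain_igraph(D)
  dd <- igraph::distances(g, weights = igraph::E(g)$weight)
  dd <- dd[rownames(coords), rownames(coords)]
  eu <- as.matrix(stats::dist(coords))
  i <- upper.tri(dd) & is.finite(dd) & dd > 0
  sum(((eu[i] - dd[i])^2) / dd[i]^2)
}

#' Embed a domain graph in 2D or 3D
#'
#' Kamada-Kawai stress minimisation against all-pairs weighted shortest-path
#' distances, initialised from graph nodes placed on a circle (in 3D the
#' circle gets seeded jitter on the third axis, since a perfectly planar
#' start is a saddle point).  Deterministic given the seed.  Disconnected
#' graphs are embedded per component, components tiled side by side.
#'
#' @param D A `domain_graph`.
#' @param dim 2 or 3.
#' @param seed Integer seed.
#' @return Coordinate matrix with rows named by node id; attribute
#'   `stress_initial` records the stress of the circular start.
#' @export
embed_domain_graph <- function(D, dim = 2L, seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(dim %in% c(2L, 3L))
  g <- domain_igraph(D)
  if (igraph::vcount(g) == 0L) stop("cannot embed an empty domain graph")
  comp <- igraph::components(g)
  coords <- matrix(NA_real_, igraph::vcount(g), dim,
                   dimnames = list(igraph::V(g)$name, NULL))
  offset <- 0
  ord <- order(-comp$csize)
  for (ci in ord) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == ci))
    init <- circular_start(sub, dim, seed)
    xy <- if (igraph::vcount(sub) <= 2L) init else
      igraph::layout_with_kk(sub, coords = init, dim = dim,
                             weights = igraph::E(sub)$weight)
    rownames(xy) <- igraph::V(sub)$name
    xy[, 1] <- xy[, 1] - min(xy[, 1]) + offset
    offset <- max(xy[, 1]) + max(5, 0.2 * (max(xy[, 1]) - min(xy[, 1])))
    coords[rownames(xy), ] <- xy
  }
  if (comp$no > 1L) {
    message(sprintf("domain graph has %d components; embedded separately",
                    comp$no))
  }
  init_all <- circular_start(g, dim, seed)
  attr(coords, "stress_initial") <- layout_stress(init_all, D)
  coords
}

#' Force-directed refinement of an embedding
#'
#' Fixed-iteration physics loop: spring attraction along graph edges toward
#' their target lengths plus weak all-pairs repulsion, to resolve residual
#' edge crossings and separate coincident nodes.  `iterations = 0` returns
#' the input unchanged.  Deterministic given the seed (used only to break
#' exactly coincident node pairs).
#'
#' @param coords Coordinate matrix from [embed_domain_graph()].
#' @param D The `domain_graph`.
#' @param iterations Number of force iterations (default 50).
#' @param seed Integer seed.
#' @param k_rep Repulsion constant (default 0.5; weak by design -- the
#'   embedding, not the refinement, carries the geometry).
#' @param step Integration step (default 0.05).
#' @return Refined coordinate matrix.
#' @export
refine_layout <- function(coords, D, iterations = 50L, seed = 1L,
                          k_rep = 0.5, step = 0.05) {
  if (iterations == 0L) return(coords)
  g <- domain_igraph(D)
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  ia <- match(el[, 1], rownames(coords))
  ib <- match(el[, 2], rownames(coords))
  x <- coords
  set.seed(seed)
  nv <- nrow(x)
  for (it in seq_len(iterations)) {
    f <- matrix(0, nv, ncol(x))
    # spring attraction along edges toward target length
    d <- x[ia, , drop = FALSE] - x[ib, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    zero <- len < 1e-9
    if (any(zero)) {
      d[zero, ] <- matrix(stats::rnorm(sum(zero) * ncol(x), sd = 1e-3),
                          ncol = ncol(x))
      len[zero] <- sqrt(rowSums(d[zero, , drop = FALSE]^2))
    }
    pull <- (len - w) / len
    fe <- d * pull
    for (k in seq_len(ncol(x))) {
      f[, k] <- f[, k] - tapply_sum(ia, fe[, k], nv) +
        tapply_sum(ib, fe[, k], nv)
    }
    # weak all-pairs repulsion (dense; fixture-scale graphs)
    dm <- as.matrix(stats::dist(x))
    diag(dm) <- Inf
    dm[dm < 1e-6] <- 1e-6
    inv3 <- k_rep / dm^3
    for (k in seq_len(ncol(x))) {
      dk <- outer(x[, k], x[, k], "-")
      f[, k] <- f[, k] + rowSums(dk * inv3)
    }
    # cap per-node displacement (temperature control against oscillation)
    disp <- step * f
    nrm <- sqrt(rowSums(disp^2))
    cap <- 0.5
    scl <- ifelse(nrm > cap, cap / nrm, 1)
    x <- x + disp * scl
  }
  x
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Assemble a guide schematic
#'
#' Bundles everything the HTML views need: coordinates, the domain graph,
#' per-staple colouring and tooltips, the scaffold routing, junction
#' ambiguity classes, and provenance (solver parameters, SP%).
#'
#' @param D A `domain_graph`.
#' @param coords Coordinates from [embed_domain_graph()] /
#'   [refine_layout()].
#' @param design The [design()].
#' @param cm The recovered [contact_map()].
#' @param ambig Optional result of [ambig_all()].
#' @param report Optional solver report (for provenance).
#' @return Object of class `guide_schematic`.
#' @export
guide_schematic <- function(D, coords, design, cm, ambig = NULL,
                            report = NULL) {
  stopifnot(all(D$nodes$id %in% rownames(coords)),
            all(is.finite(coords)))
  structure(list(D = D, coords = coords, design = design, cm = cm,
                 ambig = ambig, report = report,
                 dimension = ncol(coords)),
            class = "guide_schematic")
}

schematic_payload <- function(s, view) {
  D <- s$D
  coords <- s$coords[D$nodes$id, , drop = FALSE]
  nodes <- lapply(seq_len(nrow(D$nodes)), function(i) {
    nd <- list(id = D$nodes$id[i],
               x = round(coords[i, 1], 3), y = round(coords[i, 2], 3))
    if (ncol(coords) == 3L) nd$z <- round(coords[i, 3], 3)
    nd
  })
  staple_cols <- grDevices::hcl.colors(
    max(1L, length(s$design$staples)), "Spectral")
  seq_of <- function(e) {
    if (e$type != "ds_scaffold" || is.na(e$staple)) return(NULL)
    st <- s$design$staples[[e$staple + 1L]]
    lo <- e$sb_start - e$length + 1L
    paste(st$chars[(lo + 1L):(e$sb_start + 1L)], collapse = "")
  }
  edges <- lapply(seq_len(nrow(D$edges)), function(i) {
    e <- as.list(D$edges[i, ])
    tip <- switch(e$type,
      ds_scaffold = sprintf(
        "staple %d | scaffold (%d: %d) | section 5'->3': %s",
        e$staple, e$start + e$length - 1L, e$length, seq_of(e)),
      ss_scaffold = sprintf("single-stranded scaffold (%d: %d)",
                            e$start, e$length),
      scaffold_nick = "scaffold nick",
      staple_crossover = sprintf("staple %d crossover", e$staple),
      staple_loopout = sprintf("staple %d loop-out (%d nt)", e$staple,
                               e$length),
      staple_dangle = sprintf("staple %d dangle (%d nt)", e$staple,
                              e$length))
    col <- if (view == "staples" && !is.na(e$staple)) {
      staple_cols[e$staple + 1L]
    } else if (e$type %in% c("ds_scaffold", "ss_scaffold", "scaffold_nick")) {
      "#555555"
    } else {
      "#bbbbbb"
    }
    hide <- view == "scaffold" && e$type %in% c("staple_dangle")
    list(from = e$from, to = e$to, type = e$type, color = col,
         tooltip = tip, hidden = hide,
         length = if (is.na(e$length)) 1L else e$length,
         staple = if (is.na(e$staple)) NULL else e$staple)
  })
  junctions <- NULL
  if (view == "ambiguity" && !is.null(s$ambig) && s$ambig$n_junctions > 0) {
    jr <- s$ambig$junctions
    junctions <- lapply(seq_len(nrow(jr)), function(i) {
      node <- as.character((jr$junction[i] + 1L) %% s$D$n)
      list(node = node,
           class = if (jr$ambiguous[i]) "ambiguous" else "immovable",
           color = if (jr$ambiguous[i]) "#cc2222" else "#22aa22",
           tooltip = sprintf("junction %d|%d: slack left %d, right %d (%s)",
                             jr$junction[i], jr$junction[i] + 1L,
                             jr$slack_left[i], jr$slack_right[i],
                             ifelse(jr$ambiguous[i], "moveable", "immovable")))
    })
  }
  prov <- list(view = view, dimension = s$dimension)
  if (!is.null(s$report)) {
    prov$params <- s$report$params
    prov$sp_percent <- s$report$sp_percent
  }
  list(provenance = prov, nodes = nodes, edges = edges,
       junctions = junctions)
}

#' Export an interactive HTML guide schematic
#'
#' Writes a self-contained HTML page (inline JSON + vanilla JS/SVG; no
#' network resources) with pan, zoom, node dragging and hover tooltips
#' carrying staple ids, section sequences and scaffold base ranges.  Three
#' views: `"staples"` (per-staple colouring), `"scaffold"` (scaffold
#' routing only, staple colouring suppressed), `"ambiguity"` (junctions
#' marked green = immovable, red = moveable).
#'
#' @param schematic A [guide_schematic()].
#' @param view One of `"staples"`, `"scaffold"`, `"ambiguity"`.
#' @param path Output path.
#' @export
export_html <- function(schematic, view = c("staples", "scaffold",
                                            "ambiguity"), path) {
  view <- match.arg(view)
  payload <- jsonlite::toJSON(schematic_payload(schematic, view),
                              auto_unbox = TRUE, null = "null", digits = NA)
  html <- sub("__DATA__", payload, guide_html_template(), fixed = TRUE)
  html <- sub("__TITLE__", sprintf("origami guide schematic (%s view)", view),
              html, fixed = TRUE)
  writeLines(html, path)
  invisible(path)
}

guide_html_template <- function() {
'<!DOCTYPE html>
<html><head><meta charset="utf-8"><title>__TITLE__</title>
<style>
 body{margin:0;font:13px sans-serif}
 #tip{position:absolute;background:#222;color:#eee;padding:4px 7px;
      border-radius:3px;pointer-events:none;display:none;max-width:420px}
 svg{width:100vw;height:100vh;cursor:grab}
 .edge{stroke-width:2;fill:none}
 .node{fill:#333;cursor:pointer}
 .junction{stroke:#000;stroke-width:0.5}
</style></head><body>
<div id="tip"></div><svg id="view"></svg>
<script>
var data = __DATA__;
var svg = document.getElementById("view"), tip = document.getElementById("tip");
var NS = "http://www.w3.org/2000/svg";
var g = document.createElementNS(NS, "g"); svg.appendChild(g);
var pos = {};
data.nodes.forEach(function(n){ pos[n.id] = {x:n.x, y:(n.z===undefined? n.y : n.y + 0.35*n.z)}; });
function addTip(el, text){
  el.addEventListener("mousemove", function(ev){
    tip.style.display="block"; tip.textContent=text;
    tip.style.left=(ev.pageX+12)+"px"; tip.style.top=(ev.pageY+12)+"px";});
  el.addEventListener("mouseout", function(){ tip.style.display="none"; });
}
var edgeEls = [];
data.edges.forEach(function(e){
  if (e.hidden) return;
  var ln = document.createElementNS(NS, "line");
  ln.setAttribute("class","edge type-"+e.type);
  ln.setAttribute("stroke", e.color);
  if (e.type==="staple_crossover"||e.type==="staple_loopout"||e.type==="staple_dangle")
    ln.setAttribute("stroke-dasharray","3,2");
  addTip(ln, e.tooltip); g.appendChild(ln);
  edgeEls.push({el:ln, e:e});
});
var nodeEls = [];
data.nodes.forEach(function(n){
  var c = document.createElementNS(NS, "circle");
  c.setAttribute("class","node"); c.setAttribute("r", 2);
  addTip(c, "node "+n.id); g.appendChild(c);
  nodeEls.push({el:c, n:n});
  var drag = null;
  c.addEventListener("mousedown", function(ev){ drag = n.id; ev.stopPropagation();
    function mv(e2){ if(!drag) return;
      var p = toLocal(e2); pos[drag].x = p.x; pos[drag].y = p.y; render(); }
    function up(){ drag=null; window.removeEventListener("mousemove",mv);
      window.removeEventListener("mouseup",up); }
    window.addEventListener("mousemove",mv); window.addEventListener("mouseup",up);
  });
});
(data.junctions||[]).forEach(function(j){
  var c = document.createElementNS(NS, "circle");
  c.setAttribute("class","junction "+j.class);
  c.setAttribute("r", 4); c.setAttribute("fill", j.color);
  addTip(c, j.tooltip); g.appendChild(c);
  nodeEls.push({el:c, n:{id:j.node}});
});
var scale = 1, tx = 60, ty = 60;
function toLocal(ev){
  var r = svg.getBoundingClientRect();
  return {x:(ev.clientX-r.left-tx)/scale, y:(ev.clientY-r.top-ty)/scale};
}
function render(){
  g.setAttribute("transform","translate("+tx+","+ty+") scale("+scale+")");
  edgeEls.forEach(function(o){
    var a = pos[o.e.from], b = pos[o.e.to]; if(!a||!b) return;
    o.el.setAttribute("x1",a.x); o.el.setAttribute("y1",a.y);
    o.el.setAttribute("x2",b.x); o.el.setAttribute("y2",b.y);});
  nodeEls.forEach(function(o){
    var p = pos[o.n.id]; if(!p) return;
    o.el.setAttribute("cx",p.x); o.el.setAttribute("cy",p.y);});
}
svg.addEventListener("wheel", function(ev){ ev.preventDefault();
  scale *= (ev.deltaY<0 ? 1.1 : 0.9); render(); });
var pan = null;
svg.addEventListener("mousedown", function(ev){ pan={x:ev.clientX-tx,y:ev.clientY-ty}; });
window.addEventListener("mousemove", function(ev){
  if(pan){ tx=ev.clientX-pan.x; ty=ev.clientY-pan.y; render(); }});
window.addEventListener("mouseup", function(){ pan=null; });
render();
</script></body></html>'
}

#' Write layout coordinates as CSV
#'
#' @param coords Coordinate matrix.
#' @param path Output path.
#' @export
write_coordinates <- function(coords, path) {
  df <- data.frame(node_id = rownames(coords), coords)
  names(df)[-1] <- c("x", "y", "z")[seq_len(ncol(coords))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(coords)
}
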