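# hand-built solver state: two staples on a 60-base circular scaffold.
# staple 1 is fixed (one route over bases 0..9); staple 2 has one route
# whose single 10-base section overlaps `overlap` bases of staple 1, and an
# alternative route far away over bases 40..31.
toy_state <- function(overlap, beta) {
  sc <- scaffold(strrep("ACGT", 15))
  mk_route <- function(start, mu, offset = 0L) {
    list(sections = rbind(c(start = start, mu = mu, offset = offset)),
         bases = (start - 0:(mu - 1L)) %% sc$n)
  }
  srts <- list(
    structure(list(vid = 0L, length = 10L, routes = list(mk_route(9L, 10L)),
                   aborted = FALSE), class = "srt"),
    structure(list(vid = 1L, length = 10L,
                   routes = list(mk_route(19L - overlap, 10L),
                                 mk_route(40L, 10L)),
                   aborted = FALSE), class = "srt"))
  st <- revnano:::new_state(srts, sc$n)
  list(st = st, sc = sc,
       params = solver_params(mu_min = 6, sigma = 4, beta = beta))
}
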