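# Junction sequence-ambiguity analysis.
#
# A junction is a boundary between two adjacent hybridised scaffold bases
# that belong to different staple sections (a Holliday-junction crossover,
# a half-crossover, or a nick between two staples).  The junction can
# migrate one base if the staple flanking one side can take over the pairing
# of the first scaffold base on the other side while staying Watson-Crick
# complementary -- which reduces to a scaffold letter comparison: the
# junction is immovable exactly when the scaffold letter following the
# crossover differs from the scaffold letter on the other side of the
# crossover.  Slack is how many bases it can slide in each direction.

junction_boundaries <- function(cm) {
  n <- cm$n
  ps <- cm$partner_staple; pb <- cm$partner_base
  last_b <- if (cm$circular) n - 1L else n - 2L
  out <- integer(0)
  for (b in 0:last_b) {
    b2 <- (b + 1L) %% n
    if (is.na(ps[b + 1L]) || is.na(ps[b2 + 1L])) next
    same_section <- ps[b + 1L] == ps[b2 + 1L] && pb[b2 + 1L] == pb[b + 1L] - 1L
    if (!same_section) out <- c(out, b)
  }
  out
}

# length of the maximal same-section run containing scaffold base b
flank_section_length <- function(cm, b, dir) {
  n <- cm$n
  len <- 1L
  cur <- b
  repeat {
    nxt <- cur + dir
    if (cm$circular) nxt <- nxt %% n else if (nxt < 0L || nxt >= n) break
    if (is.na(cm$partner_staple[nxt + 1L])) break
    same <- cm$partner_staple[nxt + 1L] == cm$partner_staple[cur + 1L] &&
      cm$partner_base[nxt + 1L] == cm$partner_base[cur + 1L] - dir
    if (!same) break
    cur <- nxt
    len <- len + 1L
    if (len > n) break
  }
  len
}

#' Slack of one junction
#'
#' Quantifies how far the junction at scaffold boundary `b | b+1` can slide
#' in each direction while both flanking staples stay Watson-Crick
#' complementary to the scaffold.  A shift by `k` to the right transfers the
#' pairing of scaffold bases `b+1 ... b+k` to the left staple, which must
#' supply its `k` preceding staple bases (letters tested against the
#' scaffold regardless of hybridising/non-hybridising markup, since a
#' complementary dangle base is exactly what makes a junction ambiguous);
#' the left shift is symmetric.  The search is capped at the shorter
#' flanking section length minus one.
#'
#' @param cm A [contact_map()].
#' @param design The [design()] (supplies the fixed staple sequences).
#' @param b 0-based scaffold base index on the left of the boundary; the
#'   partner of `b` and of `b+1` must be different staple sections.
#' @return List of class `junction_report`: `junction` (= `b`),
#'   `slack_left`, `slack_right`, `ambiguous`, `staples`.
#' @export
junction_slack <- function(cm, design, b) {
  n <- cm$n
  sc <- design$scaffold
  b2 <- if (cm$circular) (b + 1L) %% n else b + 1L
  ps <- cm$partner_staple; pb <- cm$partner_base
  if (b2 >= n || is.na(ps[b + 1L]) || is.na(ps[b2 + 1L]) ||
      (ps[b + 1L] == ps[b2 + 1L] && pb[b2 + 1L] == pb[b + 1L] - 1L)) {
    stop(sprintf("scaffold boundary %d|%d is not a junction", b, b + 1L))
  }
  cap <- min(flank_section_length(cm, b, -1L),
             flank_section_length(cm, b2, +1L)) - 1L
  x <- ps[b + 1L]; p <- pb[b + 1L]        # left staple, its base at b
  y <- ps[b2 + 1L]; q <- pb[b2 + 1L]      # right staple, its base at b+1
  stx <- design$staples[[x + 1L]]
  sty <- design$staples[[y + 1L]]

  slack_right <- 0L
  for (k in seq_len(max(cap, 0L))) {
    pos <- b + k
    if (cm$circular) pos <- pos %% n else if (pos >= n) break
    sb <- p - k
    if (sb < 0L || stx$chars[sb + 1L] != sc$req[pos + 1L]) break
    slack_right <- k
  }
  slack_left <- 0L
  for (k in seq_len(max(cap, 0L))) {
    pos <- b - k + 1L
    if (cm$circular) pos <- pos %% n else if (pos < 0L) break
    sb <- q + k
    if (sb >= sty$length || sty$chars[sb + 1L] != sc$req[pos + 1L]) break
    slack_left <- k
  }
  structure(list(junction = b, slack_left = slack_left,
                 slack_right = slack_right,
                 ambiguous = slack_left + slack_right > 0L,
                 staples = sort(unique(c(x, y)))),
            class = "junction_report")
}

#' Junction ambiguity report for a whole design
#'
#' Evaluates [junction_slack()] at every junction of the contact map and
#' summarises.  When every junction is immovable *and* every staple is
#' fully placed, the contact map is unambiguously encoded in the sequences
#' (zero information loss at the topology-recovery stage), which is flagged
#' as `i2_zero`.
#'
#' @param cm A [contact_map()].
#' @param design The [design()].
#' @return List with `junctions` (data.frame: junction, slack_left,
#'   slack_right, ambiguous, staples), `n_junctions`, `n_ambiguous`,
#'   `all_placed`, `i2_zero`.
#' @export
ambig_all <- function(cm, design) {
  bs <- junction_boundaries(cm)
  reports <- lapply(bs, function(b) junction_slack(cm, design, b))
  df <- data.frame(
    junction = bs,
    slack_left = vapply(reports, `[[`, integer(1), "slack_left"),
    slack_right = vapply(reports, `[[`, integer(1), "slack_right"),
    ambiguous = vapply(reports, `[[`, logical(1), "ambiguous"),
    staples = vapply(reports, function(r) paste(r$staples, collapse = ";"),
                     character(1))
  )
  # a staple is fully placed if all its hybridising bases appear in the map
  hyb_total <- sum(vapply(design$staples, function(s) {
    sum(s$segments$length[s$segments$kind == "hybridising"])
  }, integer(1)))
  all_placed <- sum(!is.na(cm$partner_staple)) == hyb_total
  list(junctions = df,
       n_junctions = length(bs),
       n_ambiguous = sum(df$ambiguous),
       all_placed = all_placed,
       i2_zero = all_placed && sum(df$ambiguous) == 0L)
}

#' Write a junction report as CSV
#'
#' @param ambig Result of [ambig_all()].
#' @param path Output path.
#' @export
write_junction_report <- function(ambig, path) {
  utils::write.csv(ambig$junctions, path, row.names = FALSE)
  invisible(ambig)
}
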