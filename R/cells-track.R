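# Frame-to-frame particle linking in the Crocker-Grier spirit: each pair of
# consecutive frames is linked by the one-to-one assignment that maximizes
# the number of links within the displacement gate and, among those,
# minimizes the total squared displacement (equivalently: minimize
# sum(d^2) + max_disp^2 per unmatched object). The assignment is solved
# exactly by dynamic programming over column subsets, after splitting the
# feasibility graph into connected components (components are tiny in
# practice because links farther than max_disp are forbidden).

# exact min-cost assignment for one component; cost has Inf where infeasible.
# Returns per-row matched column index (NA = unmatched). Ties broken
# deterministically: rows in order, lower column index preferred.
.assign_component <- function(cost, penalty) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nc > 16)
    stop("assignment component too large (", nc, " objects); ",
         "increase gating stringency (smaller max_disp)")
  nS <- bitwShiftL(1L, nc)
  g <- rep(Inf, nS); g[1] <- 0
  choice <- matrix(-1L, nr, nS)
  for (i in seq_len(nr)) {
    g2 <- rep(Inf, nS); ch <- rep(-1L, nS)
    for (S in 0:(nS - 1L)) {
      gi <- g[S + 1L]
      if (!is.finite(gi)) next
      v <- gi + penalty                      # row i unmatched
      if (v < g2[S + 1L]) { g2[S + 1L] <- v; ch[S + 1L] <- 0L }
      for (j in seq_len(nc)) {
        cij <- cost[i, j]
        if (!is.finite(cij)) next
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(S, bit) != 0L) next
        S2 <- bitwOr(S, bit)
        v <- gi + cij
        if (v < g2[S2 + 1L]) { g2[S2 + 1L] <- v; ch[S2 + 1L] <- j }
      }
    }
    g <- g2
    choice[i, ] <- ch
  }
  pen_cols <- penalty * (nc - vapply(0:(nS - 1L), function(S)
    sum(bitwAnd(S, bitwShiftL(1L, 0:(nc - 1L))) != 0L), numeric(1)))
  S <- which.min(g + pen_cols) - 1L
  match <- rep(NA_integer_, nr)
  for (i in rev(seq_len(nr))) {
    j <- choice[i, S + 1L]
    if (j > 0L) {
      match[i] <- j
      S <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
    }
  }
  match
}

# full assignment with component splitting
.assign_gated <- function(cost, penalty) {
  nr <- nrow(cost); nc <- ncol(cost)
  match <- rep(NA_integer_, nr)
  if (nr == 0 || nc == 0) return(match)
  feas <- is.finite(cost)
  row_comp <- rep(0L, nr); col_comp <- rep(0L, nc); ncomp <- 0L
  for (r in seq_len(nr)) {
    if (row_comp[r] > 0L || !any(feas[r, ])) next
    ncomp <- ncomp + 1L
    qr <- r
    while (length(qr)) {
      r0 <- qr[1]; qr <- qr[-1]
      if (row_comp[r0] > 0L) next
      row_comp[r0] <- ncomp
      for (c0 in which(feas[r0, ] & col_comp == 0L)) {
        col_comp[c0] <- ncomp
        qr <- c(qr, which(feas[, c0] & row_comp == 0L))
      }
    }
  }
  for (k in seq_len(ncomp)) {
    rs <- which(row_comp == k); cs <- which(col_comp == k)
    m <- .assign_component(cost[rs, cs, drop = FALSE], penalty)
    match[rs] <- cs[m]
  }
  match
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame correspondence minimizing total squared displacement under
#' a maximum-displacement gate; per frame pair the assignment is the exact
#' global optimum over one-to-one matchings (unmatched objects pay
#' `max_disp^2`, so the matcher links as many objects as the gate allows and
#' then minimizes total squared displacement). Objects that find no partner
#' end their track; unmatched detections start new tracks. With
#' `memory > 0`, a track end may be re-linked across up to `memory` skipped
#' frames. Results are independent of input row order (detections are
#' processed in `frame`, then `label` order; ties in cost are broken towards
#' the lowest label index).
#'
#' @param detections Data frame with columns `frame`, `label`, `x_um`,
#'   `y_um`.
#' @param max_disp Maximum linking displacement in um.
#' @param memory Number of frames an unmatched track survives (default 0).
#' @return Data frame `frame`, `track_id`, `label`, `x_um`, `y_um`, sorted
#'   by frame then label; `track_id` is dense from 1 in order of first
#'   appearance.
#' @export
link_tracks <- function(detections, max_disp, memory = 0) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "label", "x_um", "y_um") %in% names(detections)),
            is.numeric(max_disp), max_disp > 0, memory >= 0)
  det <- detections[order(detections$frame, detections$label), , drop = FALSE]
  if (nrow(det) == 0)
    return(data.frame(frame = integer(0), track_id = integer(0),
                      label = integer(0), x_um = numeric(0),
                      y_um = numeric(0)))
  frames <- sort(unique(det$frame))
  active <- data.frame(track_id = integer(0), x = numeric(0),
                       y = numeric(0), last_frame = numeric(0))
  next_id <- 1L
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    d <- det[det$frame == f, , drop = FALSE]
    active <- active[f - active$last_frame <= memory + 1, , drop = FALSE]
    active <- active[order(active$track_id), , drop = FALSE]
    ids <- rep(NA_integer_, nrow(d))
    if (nrow(active) > 0) {
      dx <- outer(active$x, d$x_um, `-`)
      dy <- outer(active$y, d$y_um, `-`)
      cost <- dx^2 + dy^2
      cost[cost > max_disp^2] <- Inf
      m <- .assign_gated(cost, max_disp^2)
      linked <- !is.na(m)
      ids[m[linked]] <- active$track_id[linked]
      active <- active[!linked, , drop = FALSE]
    }
    new <- is.na(ids)
    if (any(new)) {
      ids[new] <- seq.int(next_id, length.out = sum(new))
      next_id <- next_id + sum(new)
    }
    out[[fi]] <- data.frame(frame = d$frame, track_id = ids,
                            label = d$label, x_um = d$x_um, y_um = d$y_um)
    active <- rbind(active,
                    data.frame(track_id = ids, x = d$x_um, y = d$y_um,
                               last_frame = f))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
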