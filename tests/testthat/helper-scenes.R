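# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code; nothing is read from disk.

test_optics <- function(pixel_size = 0.5, ...) {
  qdf_optics(pixel_size = pixel_size, ...)
}

# noise-free single bead scene (20 um disc, 3 um tall) centred in the field
bead_scene <- function(roundness = 0, puncta = NULL, noise = FALSE,
                       field = 128, centre = 32, edge_gain = 50, seed = 1L) {
  body <- qdf_body(centre, centre, radius_um = 20, height_um = 3,
                   roundness = roundness, edge_gain = edge_gain)
  qdf_scene(c(field, field), bodies = list(body),
            puncta = puncta %||% punctum(numeric(0), numeric(0))[0, ],
            shot_noise = noise, read_noise_sigma = if (noise) 2 else 0,
            phase_noise_sigma = if (noise) 0.01 else 0,
            seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# Pearson correlation from the textbook sum formula (no stats::cor)
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# slope-vs-constant F test from explicit residual sums of squares (no lm)
oracle_ftest <- function(x, y) {
  n <- length(x)
  b <- (sum(x * y) - sum(x) * sum(y) / n) / (sum(x^2) - sum(x)^2 / n)
  a <- mean(y) - b * mean(x)
  rss1 <- sum((y - a - b * x)^2)
  rss0 <- sum((y - mean(y))^2)
  f <- (rss0 - rss1) / (rss1 / (n - 2))
  list(slope = b, intercept = a, f = f,
       p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# exhaustive minimum-cost one-to-one matching between two point sets:
# cost d^2 per link (forbidden beyond max_disp), max_disp^2 per unmatched
# object on either side. Enumerates all injections of subsets of rows into
# columns. Returns the optimal total cost.
oracle_link_cost <- function(p1, p2, max_disp) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  pen <- max_disp^2
  if (n1 == 0 || n2 == 0) return(pen * (n1 + n2))
  d2 <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    d2[i, j] <- sum((p1[i, ] - p2[j, ])^2)
  best <- Inf
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  for (rows in subsets(seq_len(n1))) {
    k <- length(rows)
    if (k > n2) next
    for (cols in subsets(seq_len(n2))) {
      if (length(cols) != k) next
      for (pc in perms(cols)) {
        d <- if (k) d2[cbind(rows, pc)] else numeric(0)
        if (any(d > pen)) next
        cost <- sum(d) + pen * (n1 - k) + pen * (n2 - k)
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# total linking cost actually realised by link_tracks() on two frames
realized_link_cost <- function(det, max_disp) {
  tr <- link_tracks(det, max_disp = max_disp)
  t1 <- tr[tr$frame == 1, ]; t2 <- tr[tr$frame == 2, ]
  m <- merge(t1, t2, by = "track_id")
  linked <- nrow(m)
  cost <- if (linked) sum((m$x_um.x - m$x_um.y)^2 + (m$y_um.x - m$y_um.y)^2)
          else 0
  cost + max_disp^2 * ((nrow(t1) - linked) + (nrow(t2) - linked))
}
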