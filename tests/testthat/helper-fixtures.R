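# Shared small fixtures, built in code.

tiny_geometry <- function(nr = 8, nc = 8) build_default_geometry(nr, nc)

# A short planted session reused across tests (built once per test run).
fixture_env <- new.env()

planted_session <- function() {
  if (is.null(fixture_env$planted)) {
    g <- build_default_geometry(12, 12)
    sch <- make_gesture_schedule(30, seed = 11)
    fp <- footprint("all", c(5.5, 5.5), 2.5, amplitude_db = 4)
    fixture_env$planted <- list(
      geometry = g, schedule = sch, fp = fp,
      sim = simulate_session(g, fp, sch, seed = 21))
  }
  fixture_env$planted
}

# Brute-force TFCE oracle: explicit connected-component labelling at every
# threshold, independent of the compiled path.
tfce_bruteforce <- function(grid, H = 2, E = 1, dh = 0.1) {
  nr <- nrow(grid); nc <- ncol(grid)
  score <- matrix(0, nr, nc)
  mx <- max(grid, na.rm = TRUE)
  if (!is.finite(mx) || mx < dh) {
    score[is.na(grid)] <- NA
    return(score)
  }
  for (h in seq(dh, mx + 1e-12, by = dh)) {
    supra <- !is.na(grid) & grid >= h
    lab <- matrix(0L, nr, nc)
    cur <- 0L
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!supra[r, c] || lab[r, c] > 0) next
      cur <- cur + 1L
      queue <- list(c(r, c)); lab[r, c] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (supra[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
    if (cur > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = cur)
      add <- h^H * sizes^E * dh
      sel <- lab > 0
      score[sel] <- score[sel] + add[lab[sel]]
    }
  }
  score[is.na(grid)] <- NA
  score
}

# textbook step-up BH oracle
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
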