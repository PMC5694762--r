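# Dense minimum-cost assignment (Jonker-Volgenant shortest augmenting path,
# O(n^3)). Internal: the event matcher builds a square cost matrix with
# dummy rows/columns for unmatched events and large finite costs for gated
# pairs, so a plain square solver suffices.

# Returns an integer vector a with a[i] = column assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (n == 0L) return(integer(0))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")

  # columns are stored at index j + 1 so index 1 is the virtual start column
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j+1] = row currently assigned to column j
  way <- integer(n + 1L)
  jreal <- 2:(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- jreal[!used[jreal]]
      cur <- cost[i0, free - 1L] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  rowsol <- integer(n)
  rowsol[p[jreal]] <- jreal - 1L
  rowsol
}
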