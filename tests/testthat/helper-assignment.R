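# Exhaustive minimum-total-distance assignment via bitmask dynamic
# programming; reference oracle for the greedy per-square matcher.
# cost: n x m matrix (n <= m <= 12); returns the minimal total cost of
# assigning every row to a distinct column.
optimalAssignmentCost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 12L)
  nMask <- bitwShiftL(1L, m)
  popcount <- integer(nMask)
  for (mask in seq_len(nMask - 1L))
    popcount[mask + 1L] <- popcount[bitwShiftR(mask, 1L) + 1L] +
      bitwAnd(mask, 1L)
  dp <- rep(Inf, nMask); dp[1L] <- 0
  for (mask in order(popcount) - 1L) {
    k <- popcount[mask + 1L]
    if (k >= n || !is.finite(dp[mask + 1L])) next
    for (j in seq_len(m) - 1L) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(mask, bit) == 0L) {
        nxt <- bitwOr(mask, bit)
        v <- dp[mask + 1L] + cost[k + 1L, j + 1L]
        if (v < dp[nxt + 1L]) dp[nxt + 1L] <- v
      }
    }
  }
  min(dp[popcount == n])
}
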