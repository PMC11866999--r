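# run code under a temporary RNG state; the caller's stream is untouched
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a sub-stream seed; stays below 2^31 - 1
derive_seed <- function(seed, stream, index = 0L) {
  (as.double(seed) * 7919 + stream * 104729 + index * 1009) %% 2147483629
}

shift_array <- function(a, off, fill = 0L) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { src[[ax]] <- seq_len(d[ax] - o); dst[[ax]] <- src[[ax]] + o }
    else { src[[ax]] <- (1 - o):d[ax]; dst[[ax]] <- seq_len(d[ax] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

all_offsets_26 <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  lapply(seq_len(nrow(offs)), function(i)
    c(offs$dx[i], offs$dy[i], offs$dz[i]))
}

# binary dilation/erosion by one voxel under 26-connectivity
dilate1 <- function(a) {
  out <- a
  for (off in all_offsets_26()) out <- out | shift_array(a, off)
  array(as.integer(out), dim = dim(a))
}

erode1 <- function(a) {
  out <- a == 1L
  for (off in all_offsets_26()) out <- out & (shift_array(a, off, 0L) == 1L)
  array(as.integer(out), dim = dim(a))
}

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for disjoint
#' ones. Defined as 0 when both masks are empty.
#'
#' @param a,b [mask_volume()] objects on one grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "mask_volume"), inherits(b, "mask_volume"))
  stop_if_grid_mismatch(a$grid, b$grid)
  denom <- sum(a$data) + sum(b$data)
  if (denom == 0L) return(0)
  2 * sum(a$data & b$data) / denom
}
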