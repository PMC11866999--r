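# shared small fixtures, built in code

small_grid <- function(shape = c(8L, 8L, 8L), vox = c(2, 2, 2)) {
  template_grid(shape, vox)
}

random_mask <- function(grid, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    d <- grid$shape
    mask_volume(array(rbinom(prod(d), 1L, p), dim = d), grid)
  })
}

# mask with a single lesioned voxel
point_mask <- function(grid, at) {
  d <- array(0L, grid$shape)
  d[at[1], at[2], at[3]] <- 1L
  mask_volume(d, grid)
}

# small cohort config for fast pipeline tests
tiny_config <- function(n_subjects = 12L, ...) {
  cohort_config(grid_shape = c(16L, 18L, 16L), n_subjects = n_subjects,
                lesion_size_range = c(20L, 600L),
                critical_center = c(12L, 6L, 8L),
                critical_radii = c(2.5, 3.5, 2.5), ...)
}

# independent BFS flood fill over 26- (or 6-) connected components
flood_fill_components <- function(data, connectivity = 26L) {
  d <- dim(data)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  labels <- array(0L, d)
  lab <- 0L
  for (start in which(data == 1L)) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        nb <- co + c(offs$dx[r], offs$dy[r], offs$dz[r])
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (data[li] == 1L && labels[li] == 0L) {
          labels[li] <- lab
          queue <- c(queue, li)
        }
      }
    }
  }
  labels
}
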