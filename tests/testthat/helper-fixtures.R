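# Shared fixtures and independent oracles used across test files.

# Small default world: quick to generate, enough voxels for map-level checks.
small_config <- function(..., seed = 101L) {
  args <- utils::modifyList(
    list(n_subjects = 600L, grid_shape = c(6L, 6L, 4L), n_regions = 4L,
         effect_size = 0.25, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Cohort table augmented with the two FAMD components, as the regressions use it.
cohort_with_pcs <- function(cohort, k = 2L) {
  fm <- fit_famd(cohort$data[, cohort$indicators, drop = FALSE], k = k)
  cbind(cohort$data, famd_scores(fm))
}

# Independent recursive flood-fill over 26-neighborhoods; oracle for
# form_clusters (igraph route in the implementation).
floodfill_clusters <- function(supra3d) {
  gs <- dim(supra3d)
  visited <- array(FALSE, gs)
  comp <- array(0L, gs)
  nxt <- 0L
  idx_all <- which(supra3d)
  for (start in idx_all) {
    if (visited[start]) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (visited[cur]) next
      visited[cur] <- TRUE; comp[cur] <- nxt
      co <- arrayInd(cur, gs)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- co + c(dx, dy, dz)
        if (any(nb < 1) || any(nb > gs)) next
        lin <- nb[1] + (nb[2] - 1L) * gs[1] + (nb[3] - 1L) * gs[1] * gs[2]
        if (supra3d[lin] && !visited[lin]) stack <- c(stack, lin)
      }
    }
  }
  comp
}

# Build a stat_map object directly from an F vector (for cluster and
# enrichment tests that need controlled maps).
manual_stat_map <- function(f, grid_shape, q = 2L, df2 = 200L) {
  structure(list(f = f, p = stats::pf(f, q, df2, lower.tail = FALSE),
                 partial_r2 = f * q / (f * q + df2),
                 q = q, df2 = df2, n = df2 + q + 1L,
                 predictors = paste0("PC", seq_len(q)),
                 grid_shape = grid_shape,
                 mask = array(TRUE, grid_shape),
                 region_labels = array(1L, grid_shape)),
            class = "stat_map")
}
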