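# Shared fixtures, built once per test run.

small_spec <- function() phantom_spec(grid_shape = c(24L, 24L, 18L))

# cached default anatomy (32x32x24) and a small one for pipeline tests
.anat_cache <- new.env()
default_anatomy <- function() {
  if (is.null(.anat_cache$full)) .anat_cache$full <- make_phantom_anatomy(phantom_spec())
  .anat_cache$full
}
small_anatomy <- function() {
  if (is.null(.anat_cache$small)) .anat_cache$small <- make_phantom_anatomy(small_spec())
  .anat_cache$small
}

# independent 26-connectivity labelling through igraph, as an oracle
igraph_components <- function(supra) {
  d <- dim(supra)
  idx <- which(supra)
  if (length(idx) == 0) return(integer(0))
  co <- arrayInd(idx, d)
  key <- function(m) m[, 1] + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]
  lookup <- match(seq_len(prod(d)), idx)
  edges <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    tgt <- rep(NA_integer_, length(idx))
    tgt[ok] <- lookup[key(nb[ok, , drop = FALSE])]
    hit <- which(!is.na(tgt))
    if (length(hit)) edges <- rbind(edges, cbind(hit, tgt[hit]))
  }
  g <- igraph::graph_from_edgelist(unique(t(apply(edges, 1, sort))), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  igraph::components(g)$membership
}

nuisance9 <- function(t, seed = 1) {
  withr::with_seed(seed, {
    m <- cbind(matrix(rnorm(t * 3), t, 3), matrix(rnorm(t * 6), t, 6))
  })
  colnames(m) <- c("csf", "wm", "global", paste0("mot", 1:6))
  m
}
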