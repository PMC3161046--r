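# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

# default planted-module world: 2000 x 24, 4 modules x 100 genes,
# delta = 1, sigma = 0.2, seed 42
fixture_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- generate_planted_modules(seed = 42L)
  .fixture_cache$sim
}

fixture_centered <- function() {
  if (is.null(.fixture_cache$centered))
    .fixture_cache$centered <- preprocess(fixture_sim()$expression)
  .fixture_cache$centered
}

fixture_som <- function() {
  if (is.null(.fixture_cache$som))
    .fixture_cache$som <- train_som(fixture_centered(), som_grid(20L), seed = 42L)
  .fixture_cache$som
}

# small random centered matrix for quick property checks
random_centered <- function(n = 100L, m = 8L, seed = 1L, sd = 1) {
  vals <- somatlas:::with_seed(seed, matrix(rnorm(n * m, sd = sd), n, m,
    dimnames = list(sprintf("g%03d", seq_len(n)), sprintf("s%02d", seq_len(m)))))
  expr_matrix(vals - rowMeans(vals), "centered")
}

# independent connected-components oracle on the lattice, via igraph
igraph_components <- function(nodes, grid, connectivity = 8L) {
  if (length(nodes) <= 1L) return(length(nodes))
  edges <- integer(0)
  for (a in seq_along(nodes)) for (b in seq_along(nodes)) {
    if (a >= b) next
    dc <- abs(grid$col[nodes[a]] - grid$col[nodes[b]])
    dr <- abs(grid$row[nodes[a]] - grid$row[nodes[b]])
    adjacent <- if (connectivity == 4L) dc + dr == 1L else max(dc, dr) == 1L
    if (adjacent) edges <- c(edges, a, b)
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# brute-force hypergeometric upper tail by enumerating all size-n draws
enum_hyper_tail <- function(x, n, N_set, N_univ) {
  universe <- seq_len(N_univ)
  set <- seq_len(N_set)
  draws <- utils::combn(universe, n)
  overlaps <- colSums(matrix(draws %in% set, nrow = n))
  mean(overlaps >= x)
}
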