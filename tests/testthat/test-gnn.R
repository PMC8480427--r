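# Independent reference implementation of the message-passing recursion,
# written as explicit per-node/per-edge loops over neighbour lists. It shares
# no code with the package internals and serves as the oracle for the
# vectorized forward pass.
reference_forward <- function(params, graph, n_layers) {
  m <- graph$n_obs; n <- graph$n_feat
  relu <- function(x) pmax(x, 0)
  H <- rbind(matrix(1, m, n), diag(n))         # obs: ones; feat: one-hot
  E <- matrix(graph$edges$value, ncol = 1)
  edges <- graph$edges
  for (l in seq_len(n_layers)) {
    p <- function(nm) params[[sprintf("L%d_%s", l, nm)]]
    # aggregate messages per node
    A <- matrix(0, m + n, length(p("bm")))
    for (i in seq_len(m + n)) {
      if (i <= m) {
        inc <- which(edges$obs == i); nb <- m + edges$feat[inc]
      } else {
        inc <- which(edges$feat == i - m); nb <- edges$obs[inc]
      }
      if (!length(inc)) next
      msgs <- t(vapply(seq_along(inc), function(k)
        relu(drop(H[nb[k], ] %*% p("Wh") + E[inc[k], ] %*% p("We") + p("bm"))),
        numeric(length(p("bm")))))
      A[i, ] <- colMeans(msgs)
    }
    Hn <- t(vapply(seq_len(m + n), function(i)
      relu(drop(H[i, ] %*% p("Q1") + A[i, ] %*% p("Q2") + p("bq"))),
      numeric(length(p("bq")))))
    En <- t(vapply(seq_len(nrow(edges)), function(k)
      relu(drop(E[k, ] %*% p("P1") + Hn[edges$obs[k], ] %*% p("P2") +
                  Hn[m + edges$feat[k], ] %*% p("P3") + p("bp"))),
      numeric(length(p("bp")))))
    H <- Hn; E <- En
  }
  list(H = H, E = E)
}

reference_head <- function(params, H, u, v) {
  z <- pmax(drop(H[u, ] %*% params$H_O1u + H[v, ] %*% params$H_O1v + params$H_b1), 0)
  drop(z %*% params$H_o2) + params$H_b2
}

test_that("forward pass matches the hand-rolled oracle on a single-edge graph", {
  vals <- matrix(0.7, 1, 1, dimnames = list(NULL, "f1"))
  g <- build_graph(identity_flat(vals))
  params <- tsignn:::gnn_init_params(1, 3, 3, seed = 5)
  fw <- gnn_forward_pass(g, params, n_layers = 3)
  ref <- reference_forward(params, g, 3)
  expect_equal(fw$node_embeddings, ref$H, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fw$edge_embeddings, ref$E, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("forward pass matches the oracle on a multi-node graph with missing cells", {
  set.seed(14)
  vals <- matrix(runif(12), 4, 3)
  vals[cbind(c(1, 3), c(2, 3))] <- NA
  g <- build_graph(identity_flat(vals))
  params <- tsignn:::gnn_init_params(3, 4, 3, seed = 6)
  fw <- gnn_forward_pass(g, params, n_layers = 3)
  ref <- reference_forward(params, g, 3)
  expect_equal(fw$node_embeddings, ref$H, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fw$edge_embeddings, ref$E, tolerance = 1e-10, ignore_attr = TRUE)
  # prediction head agrees too, for every (obs, feat) pair
  model <- structure(list(params = params,
                          config = imputer_config(n_layers = 3, hidden_dim = 4),
                          d_node = 3, feature_names = g$feature_names),
                     class = "trained_imputer")
  pairs <- expand.grid(obs = 1:4, feat = 1:3)
  got <- gnn_predict_edges(g, model, pairs)
  want <- vapply(seq_len(nrow(pairs)), function(k)
    reference_head(params, ref$H, pairs$obs[k], 4 + pairs$feat[k]), numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  vals <- matrix(rnorm(12), 4, 3)
  vals[2, 1] <- NA; vals[3, 3] <- NA
  gt <- tsignn:::graph_tensors(build_graph(identity_flat(vals)))
  params <- tsignn:::gnn_init_params(gt$n, 6, 3, 42)
  keep <- rep(TRUE, gt$K)
  fg <- tsignn:::gnn_grad(params, gt, 3, keep)
  lossfn <- function(p) tsignn:::gnn_grad(p, gt, 3, keep)$loss
  set.seed(1)
  for (nm in names(params)) for (r in 1:2) {
    i <- sample(length(params[[nm]]), 1)
    h <- 1e-5
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
    num <- (lossfn(p1) - lossfn(p2)) / (2 * h)
    expect_equal(fg$grads[[nm]][i], num, tolerance = 1e-5,
                 label = sprintf("d loss / d %s[%d]", nm, i))
  }
})

test_that("mean aggregation is invariant to neighbour storage order", {
  set.seed(21)
  vals <- matrix(runif(20), 5, 4)
  g <- build_graph(identity_flat(vals))
  params <- tsignn:::gnn_init_params(4, 5, 3, seed = 9)
  fw1 <- gnn_forward_pass(g, params, n_layers = 3)
  gp <- g
  perm <- sample(nrow(g$edges))
  gp$edges <- g$edges[perm, ]
  fw2 <- gnn_forward_pass(gp, params, n_layers = 3)
  expect_equal(fw2$node_embeddings, fw1$node_embeddings, tolerance = 1e-12)
  expect_equal(fw2$edge_embeddings[order(perm), ], fw1$edge_embeddings,
               tolerance = 1e-12)
})

test_that("observation nodes with identical neighbourhoods embed identically", {
  vals <- matrix(c(0.2, 0.2, 0.9,
                   0.5, 0.5, 0.1), 3, 2)   # rows 1 and 2 identical
  g <- build_graph(identity_flat(vals))
  params <- tsignn:::gnn_init_params(2, 4, 3, seed = 2)
  fw <- gnn_forward_pass(g, params, n_layers = 3)
  expect_equal(fw$node_embeddings[1, ], fw$node_embeddings[2, ], tolerance = 1e-12)
  model <- structure(list(params = params,
                          config = imputer_config(n_layers = 3, hidden_dim = 4),
                          d_node = 2, feature_names = g$feature_names),
                     class = "trained_imputer")
  pr <- gnn_predict_edges(g, model, cbind(c(1, 2), c(1, 1)))
  expect_equal(pr[1], pr[2], tolerance = 1e-12)
})

test_that("a zeroed prediction head returns its output bias everywhere", {
  vals <- matrix(runif(6), 3, 2)
  g <- build_graph(identity_flat(vals))
  params <- tsignn:::gnn_init_params(2, 4, 2, seed = 3)
  params$H_o2[] <- 0
  params$H_b2 <- 0.37
  model <- structure(list(params = params,
                          config = imputer_config(n_layers = 2, hidden_dim = 4),
                          d_node = 2, feature_names = g$feature_names),
                     class = "trained_imputer")
  pr <- gnn_predict_edges(g, model, expand.grid(1:3, 1:2))
  expect_equal(pr, rep(0.37, 6))
  expect_error(gnn_predict_edges(g, model, cbind(4, 1)), "unknown node id")
})

test_that("training is seed-deterministic and reduces the loss", {
  set.seed(41)
  vals <- matrix(runif(80), 20, 4)
  vals[matrix(runif(80) < 0.2, 20, 4)] <- NA
  g <- build_graph(identity_flat(vals))
  cfg <- imputer_config(epochs = 200, hidden_dim = 8, seed = 7)
  m1 <- train_imputer(g, cfg)
  m2 <- train_imputer(g, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  r1 <- impute_graph(m1, g); r2 <- impute_graph(m2, g)
  expect_identical(r1$predicted, r2$predicted)
  # optimization sanity: trailing window no worse than leading window
  expect_lte(mean(tail(m1$loss_trace, 100)), mean(head(m1$loss_trace, 100)))
  # all predictions stay within a small margin of the training value range
  rng <- range(g$edges$value)
  expect_true(all(r1$predicted >= rng[1] - 0.5 & r1$predicted <= rng[2] + 0.5))
})

test_that("isolated observation nodes get finite predictions from zero aggregates", {
  vals <- matrix(runif(12), 4, 3)
  vals[2, ] <- NA                      # row 2 has no observed edges
  g <- build_graph(identity_flat(vals))
  cfg <- imputer_config(epochs = 20, hidden_dim = 6, edge_dropout = 0, seed = 1)
  m <- train_imputer(g, cfg)
  r <- impute_graph(m, g)
  expect_true(all(is.finite(r$predicted)))
})

test_that("observed cells pass through unchanged on output", {
  set.seed(8)
  vals <- matrix(runif(30), 10, 3)
  g <- build_graph(identity_flat(vals))   # fully observed
  m <- train_imputer(g, imputer_config(epochs = 15, hidden_dim = 6, seed = 2))
  r <- impute_graph(m, g)
  expect_equal(r$predicted, vals, ignore_attr = TRUE)   # exact passthrough
  expect_true(all(r$observed_mask))
})

test_that("schema mismatches between model and graph are rejected", {
  g2 <- build_graph(identity_flat(matrix(runif(8), 4, 2)))
  g3 <- build_graph(identity_flat(matrix(runif(12), 4, 3)))
  m <- train_imputer(g2, imputer_config(epochs = 5, hidden_dim = 4, seed = 1))
  expect_error(impute_graph(m, g3), "schema mismatch")
})
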