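zero_weights <- function(L, v) {
  split_lstm_weights(list(Wx = matrix(0, v, 4 * L), Wh = matrix(0, L, 4 * L),
                          b = numeric(4 * L)))
}

test_that("gate arithmetic at zero weights matches hand computation", {
  w <- zero_weights(L = 3, v = 2)
  st <- lstm_step(c(1.5, -2), NULL, w)
  expect_equal(st$c, rep(0, 3))        # i*g = 0.5 * tanh(0) = 0
  expect_equal(st$h, rep(0, 3))

  # with previous memory 1: c = f*1 = 0.5, h = o * tanh(0.5)
  st2 <- lstm_step(c(0, 0), list(h = numeric(3), c = rep(1, 3)), w)
  expect_equal(st2$c, rep(0.5, 3))
  expect_equal(st2$h, rep(0.5 * tanh(0.5), 3), tolerance = 1e-12)
  expect_equal(st2$h[1], 0.2310585786, tolerance = 1e-9)
})

test_that("vectorised step and forward agree with the scalar oracle", {
  set.seed(21)
  for (trial in 1:25) {
    L <- sample(1:4, 1); v <- sample(1:4, 1); T <- sample(1:5, 1)
    w <- random_gate_weights(L, v)
    X <- matrix(rnorm(T * v), T, v)
    H <- lstm_forward(X, w)
    expect_equal(dim(H), c(T, L))
    h <- numeric(L); c <- numeric(L)
    for (t in seq_len(T)) {
      st <- oracle_lstm_step(X[t, ], h, c, w)
      h <- st$h; c <- st$c
      expect_equal(H[t, ], h, tolerance = 1e-10)
    }
    # single-step equivalence with a random state
    s0 <- list(h = rnorm(L), c = rnorm(L))
    expect_equal(lstm_step(X[1, ], s0, w),
                 oracle_lstm_step(X[1, ], s0$h, s0$c, w), tolerance = 1e-10)
  }
})

test_that("hidden states are bounded by the sigmoid-tanh product", {
  set.seed(5)
  w <- random_gate_weights(L = 4, v = 3, scale = 3)
  H <- lstm_forward(matrix(rnorm(30, sd = 4), 10, 3), w)
  expect_true(all(abs(H) <= 1))
})

test_that("a length-one sequence reduces to a single step", {
  set.seed(9)
  w <- random_gate_weights(L = 2, v = 2)
  x <- rnorm(2)
  expect_equal(lstm_forward(matrix(x, 1), w)[1, ], lstm_step(x, NULL, w)$h)
  expect_equal(lstm_forward(matrix(rnorm(6), 3), zero_weights(2, 2)),
               matrix(0, 3, 2))
})

test_that("flatten + dense head yields calibrated probabilities", {
  H <- matrix(rnorm(8), 4, 2)
  expect_equal(flatten_dense(H, matrix(0, 8, 4), numeric(4)), rep(0.25, 4))
  expect_equal(flatten_dense(H, matrix(0, 8, 1), 0), 0.5)

  # toy with unit weights: all logits equal the sum of H, softmax uniform;
  # verify against the scalar oracle with random weights too
  H2 <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  expect_equal(flatten_dense(H2, matrix(1, 4, 2), numeric(2)), c(0.5, 0.5))
  set.seed(2)
  W <- matrix(rnorm(8), 4, 2); b <- rnorm(2)
  expect_equal(flatten_dense(H2, W, b), oracle_flatten_dense(H2, W, b),
               tolerance = 1e-12)
  p <- flatten_dense(H2, W, b)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(flatten_dense(H2, matrix(0, 5, 2), numeric(2)), "shape mismatch")
})

test_that("embedding lookup honours padding and bounds", {
  emb <- diag(4)                        # one-hot rows: output is an indicator
  X <- embed_tokens(c(2L, 0L, 3L), emb)
  expect_equal(X, rbind(c(0, 0, 1, 0), c(1, 0, 0, 0), c(0, 0, 0, 1)))
  pad <- embed_tokens(rep(0L, 5), emb)
  expect_true(all(pad == matrix(emb[1, ], 5, 4, byrow = TRUE)))
  expect_equal(dim(embed_tokens(c(1L, 1L), emb)), c(2, 4))
  expect_error(embed_tokens(4L, emb), "out of range")
})

test_that("the dimensional contract holds through the full stack", {
  for (cfg in list(c(V = 12, v = 3, T = 6, L = 2, P = 4),
                   c(V = 30, v = 5, T = 10, L = 4, P = 2),
                   c(V = 8, v = 2, T = 3, L = 3, P = 1))) {
    par <- copdatlas:::init_model_params(cfg["V"], cfg["v"], cfg["T"],
                                         cfg["L"], cfg["P"], seed = 1)
    ids <- matrix(sample(0:(cfg["V"] - 1), 5 * cfg["T"], replace = TRUE),
                  5, cfg["T"])
    X <- embed_tokens(ids[1, ], par$emb)
    expect_equal(dim(X), unname(c(cfg["T"], cfg["v"])))
    H <- lstm_forward(X, split_lstm_weights(par))
    expect_equal(dim(H), unname(c(cfg["T"], cfg["L"])))
    expect_equal(nrow(par$Wd), unname(cfg["T"] * cfg["L"]))
    p <- flatten_dense(H, par$Wd, par$bd)
    expect_length(p, cfg["P"])
    fw <- copdatlas:::forward_batch(ids, par, keep_cache = FALSE)
    expect_equal(dim(fw$Hflat), unname(c(5, cfg["T"] * cfg["L"])))
    expect_equal(dim(fw$probs), unname(c(5, cfg["P"])))
  }
})

test_that("analytic gradients match finite differences on a toy model", {
  set.seed(42)
  V <- 7; v <- 3; T <- 3; L <- 2; P <- 3; n <- 4
  par <- copdatlas:::init_model_params(V, v, T, L, P, seed = 9)
  ids <- matrix(sample(0:(V - 1), n * T, replace = TRUE), n, T)
  y <- sample(0:(P - 1), n, replace = TRUE)
  lg <- copdatlas:::loss_grad_batch(ids, y, par)
  eps <- 1e-5
  for (nm in names(par)) {
    for (i in seq_along(par[[nm]])) {
      p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (copdatlas:::loss_grad_batch(ids, y, p1, grad = FALSE)$loss -
              copdatlas:::loss_grad_batch(ids, y, p2, grad = FALSE)$loss) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-5,
                   label = sprintf("d loss / d %s[%d]", nm, i))
    }
  }
})
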