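# Model family: exact parameter accounting, forward contracts,
# re-attention and class-attention algebra, width solver.

TABLE4 <- c(cait = 120707075, deepvit = 53532867, vit_vanilla = 53532675,
            vit_224_8 = 40949763, ovitad = 38406147)

test_that("analytic counts reproduce the published table for all five models", {
  for (nm in names(TABLE4)) {
    expect_identical(count_trainable_parameters(canonical_config(nm)),
                     unname(TABLE4[nm]), label = nm)
  }
})

test_that("built-model counts equal analytic counts at both scopes", {
  for (variant in c("vanilla", "deepvit", "cait", "ovitad")) {
    cfg <- tiny_config(variant)
    m <- build_model(cfg, seed = 1)
    for (scope in c("modules", "all")) {
      expect_identical(count_trainable_parameters(m, scope),
                       count_trainable_parameters(cfg, scope))
    }
    # pure function of the config: two builds agree
    expect_identical(count_trainable_parameters(build_model(cfg, seed = 2)),
                     count_trainable_parameters(m))
  }
  # one full-size build-vs-analytic check
  m <- build_model(canonical_config("ovitad"), seed = 0)
  expect_identical(count_trainable_parameters(m), unname(TABLE4["ovitad"]))
  rm(m); gc(verbose = FALSE)
})

test_that("halving heads removes exactly 4 x embed x delta-inner per layer", {
  d16 <- count_trainable_parameters(canonical_config("vit_vanilla"))
  d8 <- count_trainable_parameters(canonical_config("vit_224_8"))
  expect_identical(d16 - d8, 6 * 4 * 1024 * (16 - 8) * 64)
})

test_that("forward pass honors the basic contracts", {
  cfg <- tiny_config("vanilla", image_size = 56L, patch_size = 8L)
  expect_identical(cfg$n_patches, 49L)        # 56/8 squared -> 50 tokens
  m <- build_model(tiny_config("ovitad"), seed = 5)
  imgs <- list(matrix(runif(45 * 54), 45), matrix(runif(14 * 14), 14))
  out <- vit_forward(m, imgs, capture_attention = TRUE)
  expect_identical(dim(out$logits), c(2L, 3L))
  # every post-softmax attention row sums to 1
  for (layer in out$attention) for (img_maps in layer) for (A in img_maps) {
    expect_lt(max(abs(rowSums(A) - 1)), 1e-10)
    expect_true(all(A >= 0))
  }
  # eval-mode determinism
  out2 <- vit_forward(m, imgs)
  expect_identical(out2$logits, out$logits)
  p <- predict_proba(m, imgs)
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-12)
  expect_error(vit_config("vanilla", image_size = 224, patch_size = 13),
               "divisible")
})

test_that("re-attention mixing: identity, permutation, shape", {
  set.seed(2)
  # 2 heads, 3 tokens: brute-force oracle
  A1 <- vitad:::softmax_rows(matrix(rnorm(9), 3))
  A2 <- vitad:::softmax_rows(matrix(rnorm(9), 3))
  maps <- list(A1, A2)
  id <- reattention(maps, diag(2))
  expect_equal(id[[1]], A1)
  expect_equal(id[[2]], A2)
  perm <- matrix(c(0, 1, 1, 0), 2)   # swap heads
  sw <- reattention(maps, perm)
  expect_equal(sw[[1]], A2)
  expect_equal(sw[[2]], A1)
  # general theta: entry-wise oracle mixed[h'] = sum_h theta[h',h] maps[h]
  theta <- matrix(rnorm(4), 2)
  mixed <- reattention(maps, theta)
  expect_equal(mixed[[1]], theta[1, 1] * A1 + theta[1, 2] * A2)
  expect_identical(dim(mixed[[2]]), dim(A2))
  expect_error(reattention(maps, diag(3)), "theta")
})

test_that("class attention: row-stochastic weights, frozen patches, 1-token oracle", {
  set.seed(3)
  pt <- matrix(rnorm(12), 4, 3)
  cls <- rnorm(3)
  out <- class_attention_forward(pt, cls)
  expect_equal(rowSums(out$weights), 1, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(out$patch_tokens, pt)
  # single patch token, no residual path, query engineered to attend to
  # it: the class update must equal that token's value projection
  one <- matrix(c(5, -2, 1), 1, 3)
  w_q <- rbind(c(1000, -400, 200), 0, 0)  # cls (1,0,0) -> query along token key
  res <- class_attention_forward(one, c(1, 0, 0), w_q = w_q, residual = FALSE)
  expect_gt(res$weights[1, 1], 0.999)
  expect_equal(as.vector(res$cls), as.vector(one), tolerance = 1e-2)
})

test_that("the width solver recovers published configurations", {
  hits <- solve_width_config(TABLE4[["ovitad"]],
                             fixed = list(variant = "ovitad", image_size = 56L,
                                          heads = 8L, depth = 6L))
  expect_true(length(hits) >= 1)
  got <- vapply(hits, function(h) h$patch_size == 14 && h$embed_dim == 1024 &&
                  h$head_dim == 64, logical(1))
  expect_true(any(got))
  expect_identical(solve_width_config(1, fixed = list(variant = "vanilla",
                                                      image_size = 224L)),
                   list())
})
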