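test_that("Wang relatedness recovers pedigree expectations", {
  set.seed(17)
  p <- runif(800, 0.15, 0.85)

  Gs <- make_pedigree_pairs(p, 15, "fullsib")
  Ks <- wang_relatedness(Gs, freq = p)
  sib_r <- vapply(seq_len(15), function(k) Ks$r[2 * k - 1, 2 * k],
                  numeric(1))
  expect_lt(abs(mean(sib_r) - 0.5), 0.03)

  Gu <- make_pedigree_pairs(p, 15, "unrelated")
  Ku <- wang_relatedness(Gu, freq = p)
  unrel_r <- vapply(seq_len(15), function(k) Ku$r[2 * k - 1, 2 * k],
                    numeric(1))
  expect_lt(abs(mean(unrel_r)), 0.02)

  # parent-offspring also estimates r ~ 0.5 (relatedness, not k-coefficients)
  Gp <- make_pedigree_pairs(p, 15, "parent-offspring")
  Kp <- wang_relatedness(Gp, freq = p)
  po_r <- vapply(seq_len(15), function(k) Kp$r[2 * k - 1, 2 * k],
                 numeric(1))
  expect_lt(abs(mean(po_r) - 0.5), 0.03)

  # exchangeability
  expect_equal(Ks$r, t(Ks$r), tolerance = 1e-12)
  # sparse pairs are flagged unreliable
  calls <- Gs$calls[1:4, 1:10]
  Gsmall <- genotype_matrix(calls, Gs$locality_of[1:4])
  Ksmall <- wang_relatedness(Gsmall)
  expect_true(all(Ksmall$unreliable[upper.tri(Ksmall$unreliable)]))
})

test_that("full-sib filtering enforces its post-condition", {
  r <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  locmap <- setNames(rep(1, 4), letters[1:4])

  r1 <- r; r1["a", "b"] <- r1["b", "a"] <- 0.5
  f1 <- filter_fullsibs(list(r = r1), locmap, seed = 1)
  expect_length(f1$removed, 1)
  expect_true(f1$removed %in% c("a", "b"))

  r2 <- r; r2["a", "b"] <- r2["b", "a"] <- 0.49
  f2 <- filter_fullsibs(list(r = r2), locmap, seed = 1)
  expect_length(f2$removed, 0)

  # triangle of mutual full-sibs: final set has no qualifying pair
  r3 <- r
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c")))
    r3[pr[1], pr[2]] <- r3[pr[2], pr[1]] <- 0.6
  f3 <- filter_fullsibs(list(r = r3), locmap, seed = 3)
  kept <- f3$retained
  expect_true(all(r3[kept, kept][upper.tri(r3[kept, kept])] < 0.5))
  expect_equal(length(f3$removed), 2)

  # cross-locality pairs are not filtered, but appear as kin edges
  locmap2 <- setNames(c(1, 2, 1, 1), letters[1:4])
  f4 <- filter_fullsibs(list(r = r1), locmap2, seed = 1)
  expect_length(f4$removed, 0)
  edges <- kin_edges(list(r = r1), locmap2, threshold = 0.35)
  expect_equal(nrow(edges), 1)
  expect_equal(sort(c(edges$id1, edges$id2)), c("a", "b"))
})

test_that("directional migration is symmetric, equivariant and normalised", {
  set.seed(23)
  base <- matrix(rbinom(10 * 200, 2, rep(runif(200, 0.2, 0.8), each = 10)),
                 10, 200)
  calls <- rbind(base, base)       # two identical localities
  third <- matrix(rbinom(10 * 200, 2, rep(runif(200, 0.2, 0.8), each = 10)),
                  10, 200)
  calls <- rbind(calls, third)
  rownames(calls) <- paste0("i", 1:30)
  G <- genotype_matrix(calls, setNames(rep(1:3, each = 10), rownames(calls)))
  M <- directional_migration(G)
  expect_equal(max(M$m, na.rm = TRUE), 1)
  # identical localities: their mutual rates are the global maximum
  expect_equal(M$m["1", "2"], 1, tolerance = 1e-6)
  expect_equal(M$m["2", "1"], 1, tolerance = 1e-6)

  # relabelling localities permutes rows and columns identically
  relabel <- c("1" = 3, "2" = 1, "3" = 2)
  G2 <- genotype_matrix(calls, setNames(relabel[as.character(
    rep(1:3, each = 10))], rownames(calls)))
  M2 <- directional_migration(G2)
  expect_equal(M2$m[as.character(relabel), as.character(relabel)],
               matrix(M$m, 3, 3,
                      dimnames = list(as.character(relabel),
                                      as.character(relabel))),
               tolerance = 1e-12)
})

test_that("directional migration matches stepwise pooled-pair arithmetic", {
  freq <- rbind(`1` = c(0.1, 0.8, 0.5), `2` = c(0.4, 0.6, 0.5),
                `3` = c(0.9, 0.1, 0.2))
  # genotypes whose sample frequencies equal freq exactly (10 ind/deme)
  calls <- NULL
  for (d in 1:3) {
    block <- sapply(freq[d, ] * 20, function(cnt) {
      g <- c(rep(2L, cnt %/% 2), rep(1L, cnt %% 2))
      c(g, rep(0L, 10 - length(g)))
    })
    calls <- rbind(calls, block)
  }
  rownames(calls) <- paste0("i", 1:30)
  G <- genotype_matrix(calls, setNames(rep(1:3, each = 10), rownames(calls)))
  M <- directional_migration(G)

  nm_into <- function(pb, pa) {                  # rate a -> b from b vs pool
    pool <- (pa + pb) / 2
    hs <- mean((2 * pb * (1 - pb) + 2 * pool * (1 - pool)) / 2)
    pm <- (pb + pool) / 2
    ht <- mean(2 * pm * (1 - pm))
    gst <- (ht - hs) / ht
    d <- 2 * (ht - hs) / (1 - hs)
    sqrt(((1 / gst - 1) / 4) * ((1 / d - 1) / 4))
  }
  raw <- matrix(NA_real_, 3, 3)
  for (a in 1:3) for (b in 1:3) if (a != b)
    raw[a, b] <- nm_into(freq[b, ], freq[a, ])
  expect_equal(unname(M$m), raw / max(raw, na.rm = TRUE), tolerance = 1e-9)
})

test_that("migration summaries and cluster comparisons are exact", {
  m <- matrix(c(NA, 0.2, 0.4,
                0.6, NA, 0.8,
                0.1, 0.3, NA), 3, 3, byrow = TRUE,
              dimnames = list(1:3, 1:3))
  s <- migration_summary(m)
  expect_equal(s$I, c(mean(c(0.6, 0.1)), mean(c(0.2, 0.3)),
                      mean(c(0.4, 0.8))))
  expect_equal(s$E, c(0.3, 0.7, 0.2))
  expect_equal(s$R_IE, s$I / s$E)

  all_eq <- matrix(0.5, 3, 3, dimnames = list(1:3, 1:3)); diag(all_eq) <- NA
  expect_true(all(migration_summary(all_eq)$R_IE == 1))

  src <- matrix(0, 3, 3, dimnames = list(1:3, 1:3)); diag(src) <- NA
  src[1, 2] <- src[1, 3] <- 0.9
  expect_equal(migration_summary(src)$R_IE[1], 0)

  # Mann-Whitney: {1,2} vs {3,4} exact
  ct <- compare_clusters(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(ct$W, 0)
  expect_equal(ct$p, 2 / 6, tolerance = 1e-12)
  expect_equal(ct$method, "exact")
  # identical groups: p in the non-significant region
  ct2 <- compare_clusters(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_gt(ct2$p, 0.9)
  expect_error(compare_clusters(1:3, c("A", "A", "A")), "two clusters")
})

test_that("R_I/E versus source distance regression is a faithful OLS", {
  loc <- data.frame(locality_id = 1:6, x = c(0, 1, 2, 3, 4, 5) * 1000,
                    y = 0)
  src <- data.frame(x = 0, y = 0)
  dists <- loc$x
  s <- data.frame(locality_id = 1:6, I = 1, E = 1,
                  R_IE = 2 - 0.0001 * dists)
  fit <- suppressWarnings(ratio_vs_source_distance(s, loc, src))
  expect_equal(fit$slope, -0.0001, tolerance = 1e-10)
  expect_lt(fit$p, 1e-10)

  # a constructed outlier flips the slope sign; Cook's distance flags it
  s2 <- s
  s2$R_IE <- 1 + 0.0001 * dists
  s2$R_IE[6] <- -10
  fit_all <- ratio_vs_source_distance(s2, loc, src)
  fit_drop <- suppressWarnings(ratio_vs_source_distance(s2, loc, src, drop = 6))
  expect_lt(fit_all$slope, 0)
  expect_gt(fit_drop$slope, 0)
  expect_equal(names(which.max(fit_all$cooks)), "6")
  expect_equal(fit_drop$slope, 0.0001, tolerance = 1e-10)

  same <- data.frame(locality_id = 1:3, x = 1000, y = 0)
  expect_error(ratio_vs_source_distance(s[1:3, ], same, src), "equal")
})
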