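# Frozen fixtures with expected values computed once with an independent
# reference implementation (scipy.stats: shapiro, ttest_rel,
# wilcoxon(method = "exact"), levene(center = "mean")).

fx_norm_a <- c(0.4370958447, 0.2435301829, 0.3363128411, 0.3632862605,
               0.3404268323, 0.2893875484, 0.4511521997, 0.2905340962,
               0.5018423714, 0.2937285901, 0.4304869654, 0.5286645393,
               0.1611139299, 0.2721211233, 0.2866678664, 0.3635950398)
fx_norm_b <- c(0.4785682571, 0.2138365203, 0.3130988332, 0.4528896609,
               0.3812276745, 0.2859482954, 0.4959946790, 0.3769743372,
               0.6086981752, 0.3308145162, 0.4727688839, 0.5257696467,
               0.2249168505, 0.3029212770, 0.3503313701, 0.4347401599)
fx_skew_a <- c(0.3238040082, 1.3917444824, 0.2222101991, 17.6635897363,
               1.8096147716, 0.2283574553, 2.4045728878, 3.7772055707,
               2.8190682794, 0.5771234425, 15.1986423261, 2.0172149562,
               0.3268568260, 0.0185653229, 7.5751689339, 0.9223039037)
fx_skew_b <- c(0.5269924433, 4.8823514197, 0.7066961026, 46.8347992730,
               6.2232724548, 0.7038893906, 4.2081548809, 1.2680789437,
               7.6313673117, 0.9097348564, 22.1219360535, 1.0254339803,
               0.3676024995, 0.0427619517, 37.0333661411, 1.4005840412)
fx_pre <- c(1.8516194828, 2.1158580084, 3.5469666513, 2.3564067131,
            2.4034301881, 3.6720519895, 2.6687329648, 1.2879510123,
            1.7505177185, 1.9434704239, 3.2792654380, 2.5878510616,
            2.6206171605, 2.3885461728, 1.8553270922, 3.7295305094)
fx_post_lin <- c(2.0493551435, 1.3100148530, 2.1104067705, 1.7581625777,
                 1.5796528882, 1.8346075256, 1.5921986655, 1.6813326312,
                 1.7124882196, 1.3939920068, 2.1513361133, 1.9460119354,
                 1.5585589189, 2.2761444763, 2.0279392664, 1.8114785551)
fx_post_svr <- c(2.4132939814, 2.4073467206, 2.3875533786, 2.3410240889,
                 2.2938711787, 2.0783309013, 1.9929130677, 1.9668351496,
                 1.8568525574, 2.0272289527, 1.6571112770, 2.8591345879,
                 2.5227866994, 1.7069119959, 1.9589903076, 1.9366706262)

test_that("Gaussian-looking samples gate to the paired t-test (oracle match)", {
  res <- compare_paired(fx_norm_a, fx_norm_b)
  expect_equal(res$test_used, "paired_t")
  expect_equal(res$gate_p_values[["a"]], 0.7528244199038172, tolerance = 1e-6)
  expect_equal(res$gate_p_values[["b"]], 0.9229095588975437, tolerance = 1e-6)
  expect_equal(res$statistic, -4.133908351895229, tolerance = 1e-6)
  expect_equal(res$df, 15)
  expect_equal(res$p_value, 0.0008834326538560411, tolerance = 1e-6)
})

test_that("skewed samples gate to the signed-rank test (oracle match)", {
  res <- compare_paired(fx_skew_a, fx_skew_b)
  expect_equal(res$test_used, "wilcoxon_signed_rank")
  expect_equal(res$gate_p_values[["a"]], 7.113348942114087e-05, tolerance = 1e-6)
  expect_equal(res$gate_p_values[["b"]], 3.358013533621442e-05, tolerance = 1e-6)
  expect_equal(res$statistic, 18)  # sum of positive signed ranks
  expect_equal(res$p_value, 0.00762939453125, tolerance = 1e-6)
})

test_that("identical samples raise the degenerate-comparison error", {
  expect_error(compare_paired(fx_norm_a, fx_norm_a), "degenerate")
  expect_error(compare_paired(fx_norm_a, fx_norm_b[1:8]), "matched")
  expect_error(compare_paired(c(1, 2), c(2, 3)), "at least 3")
})

test_that("gated selection is a deterministic function of the inputs", {
  r1 <- compare_paired(fx_skew_a, fx_skew_b)
  r2 <- compare_paired(fx_skew_a, fx_skew_b)
  expect_identical(r1, r2)
})

test_that("pooled Levene comparison matches the reference implementation", {
  res <- compare_variance(fx_pre, fx_post_lin, fx_post_svr)
  expect_equal(res$F_statistic, 10.81873540271411, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0019318766939429666, tolerance = 1e-6)
  expect_equal(res$df, c(1, 46))
  expect_equal(res$n_post, 2 * res$n_pre)
  # pooling is order-invariant
  swapped <- compare_variance(fx_pre, fx_post_svr, fx_post_lin)
  expect_equal(swapped$F_statistic, res$F_statistic)
  expect_equal(swapped$p_value, res$p_value)
})

test_that("Levene agrees with car::leveneTest(center = mean) on random data", {
  set.seed(41)
  pre <- rnorm(16, 2, 1)
  post <- rnorm(32, 2, 0.4)
  res <- compare_variance(pre, post[1:16], post[17:32])
  ref <- car::leveneTest(c(pre, post),
                         factor(rep(c("pre", "post"), c(16, 32))),
                         center = mean)
  expect_equal(res$F_statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Levene is well calibrated under the null and powered under scaling", {
  set.seed(55)
  Fs <- numeric(500); ps <- numeric(500)
  for (i in 1:500) {
    pre <- rnorm(16); post <- rnorm(32)
    r <- compare_variance(pre, post[1:16], post[17:32])
    Fs[i] <- r$F_statistic; ps[i] <- r$p_value
  }
  expect_gt(mean(Fs), 0.7); expect_lt(mean(Fs), 1.45)  # E[F(1,46)] ~ 1.05
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  # shrinking post spread tenfold about its mean is detected at n = 16
  set.seed(56)
  pre <- rnorm(16, 2, 1)
  shrink <- function(x) mean(x) + 0.1 * (x - mean(x))
  post_l <- shrink(rnorm(16, 2, 1)); post_s <- shrink(rnorm(16, 2, 1))
  expect_lt(compare_variance(pre, post_l, post_s)$p_value, 0.05)
})
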