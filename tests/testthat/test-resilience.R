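one_tree <- function(widths, years = seq(2000, length.out = length(widths)),
                     tree_id = "T1", species = "sp") {
  tibble::tibble(
    tree_id = tree_id, species = species, year = years, width_mm = widths
  )
}

test_that("Lloret indices reproduce direct ratios for both window widths", {
  # pre 4, event 2, post 3, w = 1
  tr <- one_tree(c(4, 2, 3), years = 2002:2004)
  li <- lloret_indices(tr, events = 2003, w = 1)
  expect_equal(li$rs, 0.5)
  expect_equal(li$rc, 1.5)
  expect_equal(li$rl, 0.75)

  # pre (4, 2), event 2, post (3, 3), w = 2
  tr2 <- one_tree(c(4, 2, 2, 3, 3), years = 2001:2005)
  li2 <- lloret_indices(tr2, events = 2003, w = 2)
  expect_equal(li2$rs, 2 / 3)
  expect_equal(li2$rc, 1.5)
  expect_equal(li2$rl, 1.0)

  # constant growth: all indices 1
  li3 <- lloret_indices(one_tree(rep(2, 7)), events = 2003, w = c(1, 2))
  expect_equal(li3$rs, c(1, 1))
  expect_equal(li3$rl, c(1, 1))
})

test_that("resilience equals resistance times recovery to machine precision", {
  set.seed(17)
  for (i in 1:200) {
    w <- exp(rnorm(9, sd = 0.4)) * runif(1, 0.5, 5)
    li <- lloret_indices(one_tree(w), events = 2004, w = c(1, 2))
    expect_equal(li$rl, li$rs * li$rc, tolerance = 1e-12)
  }
})

test_that("indices are invariant to rescaling the whole series", {
  w <- c(3, 4, 2, 1.5, 2.5, 3.5, 4.5)
  a <- lloret_indices(one_tree(w), events = 2003, w = c(1, 2))
  b <- lloret_indices(one_tree(w * 7.3), events = 2003, w = c(1, 2))
  expect_equal(a$rs, b$rs)
  expect_equal(a$rc, b$rc)
  expect_equal(a$rl, b$rl)
})

test_that("incomplete windows are dropped; overlapping w=2 windows warn", {
  tr <- one_tree(c(4, 2, 3, 3, 2), years = 2001:2005)
  # 2005 lacks a post year entirely
  li <- lloret_indices(tr, events = c(2003, 2005), w = 1)
  expect_equal(unique(li$event), 2003)
  # w = 2 impossible for 2004 (no 2006)
  li2 <- lloret_indices(tr, events = 2004, w = c(1, 2))
  expect_equal(li2$w, 1L)
  expect_warning(
    lloret_indices(one_tree(rep(2, 12)), events = c(2004, 2007), w = 2),
    "overlap"
  )
})

test_that("index-based computation is available as a sensitivity variant", {
  tr <- one_tree(c(4, 2, 3), years = 2002:2004)
  tr$index <- c(1.2, 0.6, 0.9)
  li <- lloret_indices(tr, events = 2003, w = 1, use = "index")
  expect_equal(li$rs, 0.5)
  expect_equal(li$rc, 1.5)
})

test_that("species summary takes medians per event and supports both averages", {
  trees <- dplyr::bind_rows(
    one_tree(c(4, 2, 3), 2002:2004, "T1"),
    one_tree(c(4, 2.8, 3), 2002:2004, "T2"),
    one_tree(c(4, 3.6, 3), 2002:2004, "T3")
  )
  li <- lloret_indices(trees, events = 2003, w = 1)
  expect_equal(sort(li$rs), c(0.5, 0.7, 0.9))
  sm <- species_summary(li)
  expect_equal(sm$value[sm$index == "rs" & sm$event == "2003"], 0.7)

  # single tree: summary equals the tree's own indices
  li1 <- lloret_indices(one_tree(c(4, 2, 3), 2002:2004), events = 2003, w = 1)
  sm1 <- species_summary(li1)
  expect_equal(sm1$value[sm1$index == "rs" & sm1$event == "2003"], 0.5)

  # the two averaging conventions agree on a single event
  p <- species_summary(li, avg = "pooled")
  m <- species_summary(li, avg = "of_medians")
  expect_equal(
    p$value[p$event == "avg"], m$value[m$event == "avg"]
  )
})

test_that("species with the milder drought multiplier resists better", {
  set.seed(55)
  wins <- 0
  for (rep in 1:20) {
    mk <- function(sp, mult, n) {
      purrr::map(seq_len(n), function(i) {
        w <- (3 * exp(-(1:26) / 12) + 3) * exp(rnorm(26, sd = 0.1))
        w[13] <- w[13] * mult
        one_tree(w, 1994:2019, sprintf("%s%02d", sp, i), sp)
      }) |> dplyr::bind_rows()
    }
    trees <- dplyr::bind_rows(mk("A", 0.9, 15), mk("B", 0.6, 15))
    sm <- species_summary(lloret_indices(trees, events = 2006, w = 1))
    rsA <- sm$value[sm$species == "A" & sm$index == "rs" & sm$event == "2006"]
    rsB <- sm$value[sm$species == "B" & sm$index == "rs" & sm$event == "2006"]
    if (rsA > rsB) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("Kruskal-Wallis H and Dunn z match hand-computed values", {
  d <- data.frame(
    v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    g = rep(c("a", "b", "c"), each = 3)
  )
  kd <- kruskal_dunn(d, "v", "g")
  expect_equal(kd$H, 7.2)
  expect_equal(kd$df, 2)
  z13 <- kd$pairwise$z[kd$pairwise$group1 == "a" & kd$pairwise$group2 == "c"]
  expect_equal(z13, -6 / sqrt(5), tolerance = 1e-10)
})

test_that("identical groups give H = 0 and no rejections", {
  d <- data.frame(v = rep(c(2, 2, 2), 3), g = rep(c("a", "b", "c"), each = 3))
  kd <- kruskal_dunn(d, "v", "g")
  expect_equal(kd$H, 0)
  expect_false(any(kd$pairwise$reject))
})

test_that("Holm-Sidak adjustment is monotone and bounded", {
  p <- c(0.001, 0.04, 0.2, 0.8)
  adj <- ringclim:::holm_sidak(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(adj[1], 1 - (1 - 0.001)^4)
  # order of adjusted values follows order of raw values
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("ties get average ranks with the standard correction in H", {
  d <- data.frame(
    v = c(1, 2, 2, 3, 3, 3, 4, 5, 6),
    g = rep(c("a", "b", "c"), each = 3)
  )
  kd <- kruskal_dunn(d, "v", "g")
  expect_equal(kd$H, unname(kruskal.test(d$v, factor(d$g))$statistic))
})

test_that("one-way ANOVA F and Tukey HSD match the textbook toy case", {
  d <- data.frame(
    v = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    g = rep(c("a", "b", "c"), each = 3)
  )
  at <- anova_tukey(d, "v", "g")
  expect_equal(at$F, 3.0)
  expect_equal(at$df, c(2, 6))
  d0 <- data.frame(v = rep(1:3, 3), g = rep(c("a", "b", "c"), each = 3))
  expect_equal(anova_tukey(d0, "v", "g")$F, 0)
})

test_that("percent decline follows directly from resistance", {
  expect_equal(growth_decline_pct(0.72), 28)
  expect_equal(growth_decline_pct(1), 0)
  expect_equal(growth_decline_pct(c(0.5, 0.25)), c(50, 75))
})
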