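deg_table <- function(degrees, genes = sprintf("G%02d", seq_along(degrees))) {
  data.frame(node = genes, degree = degrees, stringsAsFactors = FALSE)
}

test_that("hub selection uses a strict mean + k*SD cutoff with sample SD", {
  expect_equal(select_hubs(deg_table(rep(4L, 10))), character())
  expect_equal(select_hubs(deg_table(c(3, 3, 3, 3)), multiplier = 0), character())
  expect_error(select_hubs(deg_table(5)), ">= 2 nodes")

  # one outlying degree-50 node among 100 degree-2 nodes
  degrees <- c(rep(2L, 100), 50L)
  cutoff <- mean(degrees) + 2 * sd(degrees)   # independent arithmetic check
  expect_lt(cutoff, 50)
  expect_gt(cutoff, 2)
  tab <- deg_table(degrees, c(sprintf("N%03d", 1:100), "HUB"))
  expect_equal(select_hubs(tab), "HUB")

  # raising the multiplier never enlarges the hub set
  net <- main_component(generate_network(150, 600, seed = 12))
  tab2 <- centrality_table(net)
  sets <- lapply(c(0, 1, 2, 3), function(m) select_hubs(tab2, m))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("top-fraction selection takes ceiling(n * fraction) and expands boundary ties", {
  vals232 <- stats::setNames(seq(232, 1), sprintf("G%03d", 1:232))
  expect_length(select_top_fraction(vals232, 0.05), 12L)

  vals20 <- stats::setNames(stats::runif(20), sprintf("G%02d", 1:20))
  expect_length(select_top_fraction(vals20, 0.05), 1L)

  expect_equal(select_top_fraction(c(A = 5, B = 5, C = 1), 0.34), c("A", "B"))
  # a tie straddling the cut expands the selection rather than truncating
  expect_message(sel <- select_top_fraction(c(A = 5, B = 5, C = 1), 1 / 3),
                 "tie expanded")
  expect_equal(sel, c("A", "B"))

  expect_equal(sort(select_top_fraction(vals20, 1)), sort(names(vals20)))
  expect_error(select_top_fraction(numeric(), 0.05), "empty")
  expect_error(select_top_fraction(c(A = 1), 0), "fraction")
})

test_that("hub-bottleneck and crucial intersections preserve hub order", {
  tabs <- coad_tables()
  hb <- find_hub_bottlenecks(tabs$hubs, tabs$bottlenecks)
  expect_equal(hb, c("TP53", "ALB", "PRDM10", "EGFR", "AKT1", "MYC", "KRAS",
                     "SRC", "CDH1", "ITGA2", "CTNNB1"))
  expect_equal(find_hub_bottlenecks(c("A", "B"), c("C", "D")), character())
  expect_equal(find_hub_bottlenecks(c("B", "A"), c("B", "A")), c("B", "A"))

  crucial <- classify_crucial(hb, tabs$top_cc, tabs$top_stress)
  expect_equal(crucial, tabs$crucial$gene)
  expect_equal(classify_crucial(character(), tabs$top_cc, tabs$top_stress),
               character())
  expect_equal(classify_crucial(c("A", "B"), c("A", "B"), c("B", "A")),
               c("A", "B"))
})

test_that("tiering splits crucial genes at the minimum-degree tie and the largest gap", {
  tabs <- coad_tables()
  tiers <- tier_crucial(tabs$crucial$gene,
                        stats::setNames(tabs$crucial$degree, tabs$crucial$gene))
  expect_equal(names(tiers)[tiers == "potent"], c("TP53", "ALB", "PRDM10"))
  expect_equal(names(tiers)[tiers == "moderate"],
               c("EGFR", "AKT1", "MYC", "KRAS", "SRC"))
  expect_equal(names(tiers)[tiers == "weak"], c("CDH1", "CTNNB1"))

  expect_true(all(tier_crucial(c("A", "B", "C"), c(A = 5, B = 5, C = 5)) == "moderate"))

  t2 <- tier_crucial(c("A", "B", "C", "D"), c(A = 10, B = 9, C = 1, D = 1))
  expect_equal(unname(t2[c("A", "B", "C", "D")]),
               c("potent", "moderate", "weak", "weak"))

  expect_warning(t3 <- tier_crucial(c("A", "B"), c(A = 3, B = 1)), "fewer than 3")
  expect_true(all(t3 == "potent"))
  expect_error(tier_crucial(c("A", "Z"), c(A = 1)), "Z")
})

test_that("the cascade's set containments hold and the tier partition is total", {
  for (s in 1:4) {
    tab <- centrality_table(main_component(generate_network(120, 420, seed = 30 + s)))
    sel <- suppressWarnings(suppressMessages(select_genes(tab)))
    expect_true(all(sel$hub_bottlenecks %in% sel$hubs))
    expect_true(all(sel$hub_bottlenecks %in% sel$bottlenecks))
    expect_true(all(sel$crucial %in% sel$hub_bottlenecks))
    expect_true(all(sel$crucial %in% sel$top_cc))
    expect_true(all(sel$crucial %in% sel$top_stress))
    expect_equal(sort(names(sel$tiers)), sort(sel$crucial))
    expect_true(all(sel$tiers %in% c("potent", "moderate", "weak")))
  }
})

test_that("the cascade is invariant under input-row permutation", {
  tab <- centrality_table(main_component(generate_network(90, 270, seed = 77)))
  sel1 <- suppressWarnings(suppressMessages(select_genes(tab)))
  tab2 <- tab[hubnet:::.with_seed(3, sample(nrow(tab))), ]
  sel2 <- suppressWarnings(suppressMessages(select_genes(tab2)))
  expect_equal(sel1$hubs, sel2$hubs)
  expect_equal(sel1$bottlenecks, sel2$bottlenecks)
  expect_equal(sel1$crucial, sel2$crucial)
  expect_equal(sel1$tiers, sel2$tiers)
})

test_that("tier overrides replace computed tiers for named genes", {
  tabs <- coad_tables()
  sel <- selection_from_lists(tabs$hubs, tabs$bottlenecks, tabs$top_cc,
                              tabs$top_stress,
                              degrees = stats::setNames(tabs$crucial$degree,
                                                        tabs$crucial$gene),
                              tier_override = c(EGFR = "potent"))
  expect_equal(unname(sel$tiers["EGFR"]), "potent")
  expect_equal(unname(sel$tiers["TP53"]), "potent")
  expect_equal(unname(sel$tiers["CDH1"]), "weak")
})
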