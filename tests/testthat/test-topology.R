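test_that("the built-in topology partitions 1..585 into the nine regions", {
  topo <- best1_topology()
  expect_equal(topo$protein_length, 585L)
  expect_equal(topo$regions$name,
               c("IC1", "TM1", "EC1", "TM2", "IC2", "TM3", "EC2", "TM4", "IC3"))
  expect_equal(sum(topo$regions$end - topo$regions$start + 1L), 585L)
  # every residue covered exactly once
  cover <- integer(585)
  for (i in seq_len(nrow(topo$regions)))
    cover[topo$regions$start[i]:topo$regions$end[i]] <-
      cover[topo$regions$start[i]:topo$regions$end[i]] + 1L
  expect_true(all(cover == 1L))
  expect_equal(topo$subregions$ef_hand, c(312L, 323L))
  expect_equal(topo$subregions$ca_binding, c(293L, 308L))
})

test_that("invalid topologies are rejected", {
  reg <- best1_topology()$regions
  gap <- reg; gap$end[1] <- 29L
  expect_error(topology_model(gap, 585L), "partition")
  overlap <- reg; overlap$start[2] <- 30L
  expect_error(topology_model(overlap, 585L), "partition")
  short <- reg; short$end[9] <- 500L
  expect_error(topology_model(short, 585L), "partition")
  badclass <- reg; badclass$class[1] <- "XX"
  expect_error(topology_model(badclass, 585L), "class")
})

test_that("residues map to their covering region; out of range errors", {
  topo <- best1_topology()
  expect_equal(assign_region(topo, 323L), "IC3")
  expect_equal(assign_region(topo, 25L), "IC1")
  expect_equal(assign_region(topo, 60L), "EC1")
  expect_equal(assign_region(topo, c(31L, 50L, 51L, 94L, 95L)),
               c("TM1", "TM1", "EC1", "TM2", "IC2"))
  expect_error(assign_region(topo, 586L), "outside")
  expect_error(assign_region(topo, 0L), "outside")
})

test_that("topology JSON round-trips through read/write", {
  topo <- best1_topology()
  path <- withr::local_tempfile(fileext = ".json")
  write_topology_json(topo, path)
  back <- read_topology_json(path)
  expect_equal(back$regions, topo$regions)
  expect_equal(back$protein_length, topo$protein_length)
  expect_equal(lapply(back$subregions, as.integer), topo$subregions)
})

test_that("region statistics compute densities and inheritance fractions", {
  # TM1 spans 31-50 (length 20): five missense there -> prevalence 0.25
  tm1 <- do.call(rbind, lapply(31:35, function(p) mk_missense(p)))
  # IC1: 9 dominant + 1 recessive missense -> frac_dominant 0.9
  ic1 <- do.call(rbind, c(
    lapply(1:9, function(p) mk_missense(p, inheritance = "dominant")),
    list(mk_missense(10, inheritance = "recessive"))))
  stats <- region_statistics(best1_topology(), rbind(tm1, ic1))
  r <- stats$regions
  expect_equal(r$missense_prevalence[r$region == "TM1"], 5 / 20)
  expect_equal(r$frac_dominant[r$region == "IC1"], 0.9)
  expect_equal(r$frac_recessive[r$region == "IC1"], 0.1)
  expect_equal(r$n_total[r$region == "ALL"], 15)
  expect_equal(r$length[r$region == "ALL"], 585L)
})

test_that("splice records stay out of densities but are counted separately", {
  placed <- mk_missense(100)
  splice <- mk_variants("c.1740-1G>C", type = "splicing",
                        inheritance = "recessive",
                        disease = "AR_bestrophinopathy")
  stats <- region_statistics(best1_topology(), rbind(placed, splice))
  expect_equal(stats$n_splice_unplaced, 1L)
  r <- stats$regions
  expect_equal(sum(r$n_total[r$region != "ALL"]) + stats$n_splice_unplaced, 2)
})

test_that("region statistics are invariant under record permutation", {
  sim <- simulate_catalogue(seed = 47)
  df <- apply_filters(sim$variants)$retained
  s1 <- region_statistics(best1_topology(), df)
  set.seed(1); s2 <- region_statistics(best1_topology(),
                                       df[sample(nrow(df)), , drop = FALSE])
  expect_equal(s1$regions, s2$regions)
})

test_that("planted dominant-rich and recessive-rich regions are recovered", {
  sim <- simulate_catalogue(seed = 7)
  df <- apply_filters(sim$variants)$retained
  stats <- region_statistics(best1_topology(), df)
  hs <- hotspot_report(stats, prevalence_threshold = 0,
                       dominance_threshold = 0.75)
  expect_true(all(c("IC1", "TM2", "IC3") %in% hs$dominant))
  expect_true(all(c("TM1", "TM4") %in% hs$recessive))
  expect_false(any(hs$dominant %in% hs$recessive))
})

test_that("hotspot thresholds behave at the extremes", {
  sim <- simulate_catalogue(seed = 7)
  df <- apply_filters(sim$variants)$retained
  stats <- region_statistics(best1_topology(), df)
  r <- stats$regions[stats$regions$region != "ALL", ]
  # prevalence threshold above every region's density -> nothing flagged
  none <- hotspot_report(stats,
                         prevalence_threshold =
                           max(r$missense_prevalence) + 0.01,
                         dominance_threshold = 0)
  expect_length(none$dominant, 0L)
  expect_length(none$recessive, 0L)
  # zero thresholds -> every region with >= 1 missense appears somewhere
  all_hit <- hotspot_report(stats, prevalence_threshold = 0,
                            dominance_threshold = 0)
  expect_setequal(union(all_hit$dominant, all_hit$recessive),
                  r$region[r$n_missense > 0 &
                             (!is.na(r$frac_dominant) &
                                (r$frac_dominant > 0 | r$frac_recessive > 0))])
  expect_error(hotspot_report(stats, dominance_threshold = 1.01), "\\[0, 1\\]")
})

test_that("allele weighting changes densities but not region structure", {
  heavy <- mk_missense(40, allele_count = 10L)
  light <- mk_missense(41, allele_count = 1L)
  s_m <- region_statistics(best1_topology(), rbind(heavy, light))
  s_a <- region_statistics(best1_topology(), rbind(heavy, light),
                           weight = "alleles")
  expect_equal(s_m$regions$n_missense[s_m$regions$region == "TM1"], 2)
  expect_equal(s_a$regions$n_missense[s_a$regions$region == "TM1"], 11)
})

test_that("lollipop table lists placed mutations in residue order", {
  df <- rbind(mk_missense(300), mk_missense(12),
              mk_variants("c.1740-1G>C", type = "splicing",
                          inheritance = "recessive",
                          disease = "AR_bestrophinopathy"))
  lp <- lollipop_table(df)
  expect_equal(lp$aa_position, c(12L, 300L))
  expect_equal(names(lp),
               c("aa_position", "mutation_type", "inheritance", "disease"))
})
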