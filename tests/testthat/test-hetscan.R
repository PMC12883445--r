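hetscan_fixture <- function() {
  # 3 sites: exonic SNV, intronic SNV, exonic indel; 3 hemizygous-expected
  # samples, all het with VAF 0.5
  sites <- data.frame(
    contig = "chrX",
    pos = c(3000100L, 3000200L, 3000300L),
    ref = c("A", "C", "G"),
    alt = c("T", "G", "GA"),
    stringsAsFactors = FALSE
  )
  geno_matrix(
    sites, paste0("M", 1:3),
    codes = matrix(1L, 3, 3),
    af = matrix(0.5, 3, 3)
  )
}

exons_fixture <- function() {
  region_set(contig = c("chrX", "chrX"), start = c(3000050L, 3000250L),
             end = c(3000150L, 3000350L), label = c("exon1", "exon2"))
}

test_that("only exonic SNV het calls inside the window are tallied", {
  tabs <- het_scan(hetscan_fixture(), paste0("M", 1:3), exons_fixture(),
                   windows = list(c(45, 55)))
  tab <- tabs[["45-55"]]
  expect_equal(tab$unique_het_positions, 1L) # intronic and indel excluded
  expect_equal(tab$n_calls, 3L)
  expect_equal(tab$per_position$n_samples, 3L)
  expect_equal(tab$per_position$pos, 3000100L)
})

test_that("hetscan rejects input without allele fractions and unknown samples", {
  gm <- make_gm(matrix(1L, 2, 1))
  expect_error(het_scan(gm, "S1", exons_fixture()), "allele fractions")
  expect_error(het_scan(hetscan_fixture(), "NOPE", exons_fixture()), "NOPE")
  expect_error(het_scan(hetscan_fixture(), "M1", region_set()), "empty")
})

test_that("calls in overlapping genes count in every overlapping gene", {
  genes <- region_set(
    contig = c("chrX", "chrX", "chrX"),
    start = c(3000050L, 3000090L, 3100000L),
    end = c(3000150L, 3000150L, 3100100L),
    label = c("GENEA", "GENEB", "DECOY")
  )
  tab <- het_scan(hetscan_fixture(), paste0("M", 1:3), exons_fixture(),
                  windows = list(c(25, 75)))[[1]]
  tg <- top_genes(tab, genes)
  expect_equal(tg$gene, c("GENEA", "GENEB")) # tie broken lexicographically
  expect_equal(tg$count, c(3L, 3L))
  # empty table gives an empty ranking
  none <- het_scan(hetscan_fixture(), paste0("M", 1:3), exons_fixture(),
                   windows = list(c(0, 1)))[[1]]
  expect_equal(nrow(top_genes(none, genes)), 0L)
})

test_that("region densities are calls per Mb of labeled span", {
  pos <- seq(1000100L, 1900100L, length.out = 10)
  gm <- geno_matrix(
    data.frame(contig = "chrX", pos = as.integer(pos), ref = "A", alt = "T",
               stringsAsFactors = FALSE),
    "M1", codes = matrix(1L, 10, 1), af = matrix(0.5, 10, 1)
  )
  exons <- region_set("chrX", 1L, 3000000L, label = "allexon")
  tab <- het_scan(gm, "M1", exons, windows = list(c(25, 75)))[[1]]
  regions <- region_set(
    contig = c("chrX", "chrX"),
    start = c(1000001L, 2500000L),
    end = c(3000000L, 2599999L),
    label = c("big2mb", "empty100kb")
  )
  dens <- region_density(tab, regions)
  expect_equal(dens$density_per_mb[dens$region == "big2mb"], 5.0)
  expect_equal(dens$density_per_mb[dens$region == "empty100kb"], 0.0)
  expect_equal(dens$span_mb, c(2, 0.1))
})

test_that("nested regions tally independently via brute-force overlap", {
  set.seed(33)
  n <- 40
  gm <- make_gm(matrix(sample(c(1L, 0L, 2L), n * 2, TRUE), n, 2),
                pos = sort(sample(3000000:3100000, n)),
                af = matrix(runif(n * 2), n, 2))
  exons <- region_set("chrX", 3000000L, 3100000L, label = "E")
  regions <- region_set(
    contig = rep("chrX", 3),
    start = c(3000000L, 3020000L, 3040000L),
    end = c(3100000L, 3080000L, 3060000L), # nested inside one another
    label = c("outer", "mid", "inner")
  )
  tab <- het_scan(gm, c("S1", "S2"), exons, windows = list(c(25, 75)))[[1]]
  dens <- region_density(tab, regions)
  for (k in seq_len(nrow(regions))) {
    brute <- 0L
    for (r in seq_len(nrow(tab$calls))) {
      if (tab$calls$pos[r] >= regions$start[k] &&
          tab$calls$pos[r] <= regions$end[k]) brute <- brute + 1L
    }
    expect_equal(dens$n_calls[dens$region == regions$label[k]], brute)
  }
})

test_that("hetscan matches a brute-force triple loop on a random fixture", {
  set.seed(44)
  n <- 50
  samples <- paste0("M", 1:4)
  pos <- sort(sample(3000000:3005000, n))
  ref <- sample(c("A", "C"), n, TRUE)
  alt <- sample(c("T", "G", "TA"), n, TRUE, prob = c(0.4, 0.4, 0.2))
  codes <- matrix(sample(c(0L, 1L, 2L, NA), n * 4, TRUE), n, 4)
  af <- matrix(round(runif(n * 4), 2), n, 4)
  gm <- geno_matrix(
    data.frame(contig = "chrX", pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    samples, codes = codes, af = af
  )
  exons <- region_set(
    contig = rep("chrX", 2), start = c(3000000L, 3003000L),
    end = c(3002000L, 3004000L), label = c("e1", "e2")
  )
  windows <- list(c(25, 75), c(33, 66), c(45, 55))
  tabs <- het_scan(gm, samples, exons, windows = windows)
  for (w in windows) {
    brute_positions <- character()
    brute_calls <- 0L
    for (j in seq_along(samples)) {
      for (i in seq_len(n)) {
        snv <- nchar(ref[i]) == 1 && nchar(alt[i]) == 1
        exonic <- (pos[i] >= 3000000 && pos[i] <= 3002000) ||
          (pos[i] >= 3003000 && pos[i] <= 3004000)
        het <- !is.na(codes[i, j]) && codes[i, j] == 1L
        inwin <- !is.na(af[i, j]) && af[i, j] >= w[1] / 100 && af[i, j] <= w[2] / 100
        if (snv && exonic && het && inwin) {
          brute_calls <- brute_calls + 1L
          brute_positions <- union(brute_positions, as.character(pos[i]))
        }
      }
    }
    tab <- tabs[[paste(w, collapse = "-")]]
    expect_equal(tab$n_calls, brute_calls, info = paste(w, collapse = "-"))
    expect_equal(tab$unique_het_positions, length(brute_positions))
    expect_equal(sum(tab$per_position$n_samples), tab$n_calls)
  }
  # window nesting: tighter windows never gain calls anywhere
  expect_lte(tabs[["45-55"]]$n_calls, tabs[["33-66"]]$n_calls)
  expect_lte(tabs[["33-66"]]$n_calls, tabs[["25-75"]]$n_calls)
})

test_that("injected trap intervals dominate the gene ranking", {
  traps <- region_set(
    contig = c("chrX", "chrX"),
    start = c(30000000L, 90000000L),
    end = c(31000000L, 91000000L),
    label = c("TRAPGENE1", "TRAPGENE2")
  )
  ped <- data.frame(id = paste0("M", 1:6), father = NA_character_,
                    mother = NA_character_, sex = "XY", stringsAsFactors = FALSE)
  sim <- simulate_cohort(sim_config(
    pedigree = ped, n_sites_autosome = 0, n_sites_x = 3000, par_fraction = 0,
    pseudo_het_rate = 0, trap_intervals = traps, genotype_error = 0, seed = 55
  ))
  exons <- region_set("chrX", 2781479L, 153925834L, label = "allX")
  genes <- region_set(
    contig = rep("chrX", 4),
    start = c(traps$start, 50000000L, 120000000L),
    end = c(traps$end, 51000000L, 121000000L),
    label = c(traps$label, "DECOY1", "DECOY2")
  )
  tabs <- het_scan(sim$gm, ped$id, exons)
  tg <- top_genes(tabs[["25-75"]], genes)
  expect_setequal(utils::head(tg$gene, 2), c("TRAPGENE1", "TRAPGENE2"))
  # every injected pseudo-het call lies in a trap
  expect_true(all(tabs[["25-75"]]$calls$pos %in%
                    sim$gm$sites$pos[IRanges::overlapsAny(
                      xhetkin:::sites_granges(sim$gm$sites$contig, sim$gm$sites$pos),
                      xhetkin:::regions_granges(traps))]))
})
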