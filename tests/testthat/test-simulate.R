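test_that("hemizygosity holds by construction in an error-free trio", {
  sim <- simulate_cohort(sim_config(genotype_error = 0, pseudo_het_rate = 0,
                                    n_sites_autosome = 100, n_sites_x = 500,
                                    seed = 2))
  xh <- xhet_batch(sim$gm, params = filter_params(af_min = 0, dp_min = 0))
  sex <- sim$truth$sex
  expect_true(all(xh$xhet[sex[xh$sample] == "XY"] == 0))
  expect_true(all(xh$xhet[sex[xh$sample] == "XX"] > 0))
  # non-PAR X male emission is haploid by default, diploid on request
  xnp <- in_region(sim$gm$sites$contig, sim$gm$sites$pos, nonpar_x_interval())
  male_gt <- sim$gm$gt[xnp, names(sex)[sex == "XY"][1]]
  expect_true(all(male_gt %in% c("0", "1")))
  sim2 <- simulate_cohort(sim_config(genotype_error = 0, pseudo_het_rate = 0,
                                     n_sites_autosome = 0, n_sites_x = 100,
                                     par_fraction = 0,
                                     diploid_male_x = TRUE, seed = 2))
  male_gt2 <- sim2$gm$gt[, "father1"]
  expect_true(all(male_gt2 %in% c("0/0", "1/1")))
})

test_that("the same seed reproduces the emitted VCF byte for byte", {
  cfg <- sim_config(n_sites_autosome = 150, n_sites_x = 150, seed = 9)
  p1 <- tempfile(fileext = ".vcf")
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_cohort(cfg)$gm, p1)
  write_vcf(simulate_cohort(cfg)$gm, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the output
  p3 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_cohort(sim_config(n_sites_autosome = 150, n_sites_x = 150,
                                       seed = 10))$gm, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("offspring genotypes are Mendelian-consistent without error", {
  sim <- simulate_cohort(sim_config(genotype_error = 0, pseudo_het_rate = 0,
                                    n_sites_autosome = 400, n_sites_x = 0,
                                    seed = 14))
  compatible <- function(child, f, m) {
    # enumerate transmissible allele pairs from parent codes
    from <- function(code) switch(code + 1L, 0L, c(0L, 1L), 1L)
    any(outer(from(f), from(m), `+`) == child)
  }
  ped <- sim$truth$pedigree
  for (r in which(!is.na(ped$father))) {
    child <- ped$id[r]
    for (i in seq_len(nrow(sim$gm$sites))) {
      expect_true(compatible(sim$gm$codes[i, child],
                             sim$gm$codes[i, ped$father[r]],
                             sim$gm$codes[i, ped$mother[r]]))
    }
  }
})

test_that("pedigree validation rejects unknown or misordered parents", {
  bad <- data.frame(id = c("kid", "dad"), father = c("dad", NA),
                    mother = c("ghost", NA), sex = c("XY", "XY"),
                    stringsAsFactors = FALSE)
  expect_error(sim_config(pedigree = bad), "unknown parent|precede")
  misordered <- data.frame(id = c("kid", "dad", "mum"),
                           father = c("dad", NA, NA),
                           mother = c("mum", NA, NA),
                           sex = c("XY", "XY", "XX"), stringsAsFactors = FALSE)
  expect_error(sim_config(pedigree = misordered), "precede")
})

test_that("swap injection exchanges columns and is an involution", {
  sim <- simulate_cohort(sim_config(n_sites_autosome = 80, n_sites_x = 80, seed = 6))
  gm <- sim$gm
  swapped <- inject_swap(gm, c("mother1", "father1"))
  expect_equal(swapped$codes[, "mother1"], gm$codes[, "father1"],
               ignore_attr = TRUE)
  expect_equal(swapped$samples, gm$samples) # header names unchanged
  expect_identical(inject_swap(swapped, c("mother1", "father1"))$codes, gm$codes)
  expect_identical(inject_swap(gm, c("son1", "son1"))$codes, gm$codes)
})

test_that("expected_xhet has the closed-form values and limits", {
  expect_equal(expected_xhet(rep(0.5, 10)), 2 / 3)
  expect_gt(expected_xhet(rep(1e-4, 100)), 0.999) # rare-variant limit
  expect_equal(expected_xhet(1), 0)               # fixed alt: all hom-alt
})

test_that("pseudo-het truth is consistent with the emitted matrix", {
  traps <- region_set("chrX", 40000000L, 45000000L, label = "T1")
  sim <- simulate_cohort(sim_config(
    n_sites_autosome = 0, n_sites_x = 1000, par_fraction = 0,
    genotype_error = 0, trap_intervals = traps, seed = 27
  ))
  ph <- sim$truth$pseudo_het
  expect_gt(nrow(ph), 0)
  for (r in seq_len(nrow(ph))) {
    expect_equal(sim$gm$codes[ph$site[r], ph$sample[r]], 1L)
    expect_equal(sim$gm$gt[ph$site[r], ph$sample[r]], "0/1")
  }
  # pseudo-het VAF concentrates near 0.5 (inside the widest scan window)
  afs <- mapply(function(s, sm) sim$gm$af[s, sm], ph$site, ph$sample)
  expect_gt(mean(afs >= 0.25 & afs <= 0.75), 0.95)
})

test_that("an X-homozygosity run reduces Xhet without erasing it", {
  ped <- data.frame(id = c(paste0("F", 1:4), "ROH"), father = NA_character_,
                    mother = NA_character_, sex = "XX", stringsAsFactors = FALSE)
  sim <- simulate_cohort(sim_config(
    pedigree = ped, n_sites_autosome = 0, n_sites_x = 1500, par_fraction = 0,
    genotype_error = 0, pseudo_het_rate = 0,
    roh = data.frame(sample = "ROH", fraction = 0.4), seed = 35
  ))
  xh <- xhet_batch(sim$gm, params = filter_params(af_min = 0, dp_min = 0))
  roh_xhet <- xh$xhet[xh$sample == "ROH"]
  other <- xh$xhet[xh$sample != "ROH"]
  expect_lt(roh_xhet, min(other)) # reduced
  expect_gt(roh_xhet, 0.25)       # but nowhere near the hemizygous cluster
  expect_equal(sim$truth$roh$n_sites, round(0.4 * 1500))
})

test_that("write_cohort emits VCF, truth tables and the trap BED", {
  traps <- region_set("chrX", 40000000L, 45000000L, label = "T1")
  sim <- simulate_cohort(sim_config(n_sites_autosome = 50, n_sites_x = 200,
                                    trap_intervals = traps,
                                    swap_pairs = list(c("mother1", "father1")),
                                    seed = 41))
  dir <- tempfile()
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(read_vcf(paths[["vcf"]])$sites), 250L)
  bed <- load_bed(paths[["traps"]])
  expect_equal(bed$start, 40000000L)
  expect_equal(bed$end, 45000000L)
  sw <- read.delim(paths[["swaps"]])
  expect_equal(sw$sample_a, "mother1")
})
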