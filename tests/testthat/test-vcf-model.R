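test_that("genotype classification follows the het / hom-alt / missing rules", {
  cases <- list(
    list(gt = "0/1", want = "het"),
    list(gt = "1/1", want = "hom-alt"),
    list(gt = "1/2", want = "het"),
    list(gt = "./1", want = "missing"),
    list(gt = "1/.", want = "missing"),
    list(gt = "./.", want = "missing"),
    list(gt = "0/0", want = "hom-ref"),
    list(gt = "2/2", want = "hom-alt"),
    list(gt = "1", want = "hom-alt"),
    list(gt = "0", want = "hom-ref"),
    list(gt = ".", want = "missing")
  )
  for (cs in cases) expect_equal(classify_genotype(cs$gt), cs$want, info = cs$gt)
  expect_equal(classify_genotype(genotype_call("0/1")), "het")
})

test_that("classification ignores phasing separator and allele order", {
  variants <- c("0/1", "0|1", "1/0", "1|0")
  expect_true(all(classify_genotype(variants) == "het"))
  expect_equal(classify_genotype("1|2"), classify_genotype("2/1"))
  expect_equal(classify_genotype("0|0"), classify_genotype("0/0"))
})

test_that("malformed genotypes raise a parse error naming the context", {
  expect_error(classify_genotype("a/b"), "malformed genotype")
  expect_error(classify_genotype("0/1/2"), "malformed genotype")
  expect_error(
    xhetkin:::genotype_code("x", samples = "S9", sites = "chrX:5:A:T"),
    "S9.*chrX:5"
  )
})

test_that("allele fraction is the non-reference share of AD", {
  expect_equal(allele_fraction(c(10, 10)), 0.5)
  expect_equal(allele_fraction(c(0, 20)), 1.0)
  expect_equal(allele_fraction("15,3,2"), 0.25) # (3+2)/20
  expect_true(is.na(allele_fraction("30")))     # single entry: undefined
  expect_true(is.na(allele_fraction("0,0")))    # zero total: undefined
  expect_true(is.na(allele_fraction(NA_character_)))
  expect_equal(allele_fraction(genotype_call("0/1", ad = c(10, 10))), 0.5)
})

test_that("read_vcf parses sites, samples and FORMAT fields", {
  gm <- read_vcf(toy_vcf())
  expect_s3_class(gm, "geno_matrix")
  expect_equal(dim(gm), c(12L, 1L))
  expect_equal(gm$samples, "TOY1")
  expect_equal(gm$sites$pos[1], 2781478L)
  expect_equal(unname(gm$dp[2, 1]), 30)
  expect_equal(unname(gm$gq[2, 1]), 99)
  expect_equal(unname(gm$af[3, 1]), 0.25)
  # absent-call rows are missing, half-call too
  expect_true(all(is.na(gm$codes[c(8, 9), 1])))
})

test_that("read_vcf region restriction uses inclusive bounds", {
  body <- sprintf("chrX\t%d\t.\tA\tT\t50\tPASS\t.\tGT\t0/1", c(99L, 100L, 200L, 201L))
  p <- write_temp_vcf(vcf_text(body, format_defs = "GT"))
  gm <- read_vcf(p, region = interval("chrX", 100, 200))
  expect_equal(gm$sites$pos, c(100L, 200L))
  gm2 <- read_vcf(p, region = "chrX:100-200")
  expect_equal(gm2$sites$pos, c(100L, 200L))
})

test_that("haploid male X calls parse and code as hemizygous genotypes", {
  body <- c(
    "chrX\t3000000\t.\tA\tT\t50\tPASS\t.\tGT:DP\t1:30",
    "chrX\t3000001\t.\tC\tG\t50\tPASS\t.\tGT:DP\t0:25"
  )
  gm <- read_vcf(write_temp_vcf(vcf_text(body, format_defs = c("GT", "DP"))))
  expect_equal(unname(gm$codes[, 1]), c(2L, 0L))
  expect_equal(unname(gm$gt[, 1]), c("1", "0"))
})

test_that("a VCF without GT is rejected; unreadable path errors", {
  body <- "chrX\t100\t.\tA\tT\t50\tPASS\t.\tDP\t30"
  expect_error(read_vcf(write_temp_vcf(vcf_text(body, format_defs = "DP"))),
               "GT")
  expect_error(read_vcf(tempfile()), "cannot read")
})

test_that("merge builds the union of sites with missing for absent samples", {
  mk <- function(pos, codes, sample) {
    make_gm(matrix(codes, ncol = 1), pos = pos, samples = sample)
  }
  a <- mk(c(101L, 102L), c(1L, 1L), "A")
  b <- mk(c(102L, 103L), c(2L, 0L), "B")
  m <- merge_samples(list(a, b))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$sites$pos, c(101L, 102L, 103L))
  expect_true(is.na(m$codes[3, "A"])) # A has no record at s3
  expect_true(is.na(m$codes[1, "B"])) # B has no record at s1
  expect_equal(unname(m$codes[2, ]), c(1L, 2L)) # het vs hom-alt at shared site
})

test_that("merging identical site sets leaves no missing entries", {
  a <- make_gm(matrix(c(0L, 1L, 2L), ncol = 1), samples = "A")
  b <- make_gm(matrix(c(2L, 1L, 0L), ncol = 1), samples = "B")
  m <- merge_samples(list(a, b))
  expect_false(anyNA(m$codes))
})

test_that("merge rejects duplicate sample ids", {
  a <- make_gm(matrix(1L), samples = "A")
  expect_error(merge_samples(list(a, a)), "duplicate sample id")
})

test_that("merged site count equals the union of input site-key sets", {
  set.seed(42)
  for (rep in 1:5) {
    universe <- sort(sample.int(5000, 60)) + 3000000L
    gms <- lapply(1:3, function(k) {
      pos <- sort(sample(universe, sample(10:50, 1)))
      make_gm(matrix(sample(0:2, length(pos), TRUE), ncol = 1),
              pos = pos, samples = paste0("S", k))
    })
    m <- merge_samples(gms)
    expect_equal(nrow(m$sites),
                 length(unique(unlist(lapply(gms, function(g) g$sites$pos)))))
  }
})

test_that("VCF write/read round-trip reproduces genotype codes exactly", {
  set.seed(7)
  codes <- rand_code_matrix(40, 3, miss = 0.15)
  gm <- make_gm(codes, samples = c("A", "B", "C"),
                dp = matrix(30, 40, 3), gq = matrix(90, 40, 3))
  p <- tempfile(fileext = ".vcf")
  write_vcf(gm, p)
  back <- read_vcf(p)
  expect_equal(unname(back$codes), unname(codes))
  expect_equal(back$samples, gm$samples)
  # haploid genotypes survive the round trip verbatim
  sim <- simulate_cohort(sim_config(n_sites_autosome = 50, n_sites_x = 80,
                                    genotype_error = 0, seed = 3))
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(sim$gm, p2)
  back2 <- read_vcf(p2)
  expect_equal(unname(back2$codes), unname(sim$gm$codes))
  expect_true(any(back2$gt %in% c("0", "1")))
})
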