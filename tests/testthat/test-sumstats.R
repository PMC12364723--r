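test_that("well-formed file reads fully; invalid rows are dropped and reported", {
  f <- tempfile(fileext = ".tsv")
  df <- make_records(beta = c(0.1, -0.2, 0.05), se = c(0.02, 0.04, 0.01))
  write_sumstats(df, f)
  got <- read_sumstats(f)
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "n_dropped"), 0)
  expect_equal(got$beta, df$beta)

  df2 <- df; df2$se[2] <- 0
  write_sumstats(df2, f)
  got2 <- read_sumstats(f)
  expect_equal(nrow(got2), 2)
  expect_equal(attr(got2, "n_dropped"), 1)
  expect_equal(attr(got2, "drop_report")$reason, "nonpositive_se")
})

test_that("OR-scale input is stored as log(OR); OR 1 maps to beta 0", {
  f <- tempfile(fileext = ".tsv")
  df <- make_records(beta = c(1.0, 1.5), se = c(0.02, 0.04), pval = c(0.5, 0.01))
  write_sumstats(df, f)
  got <- read_sumstats(f, or_scale = TRUE)
  expect_equal(got$beta, c(0, log(1.5)))
})

test_that("missing mandatory column is a fatal configuration error", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tPOS", "rs1\t1\t100"), f)
  expect_error(read_sumstats(f), "missing mandatory column")
})

test_that("absent SE column is imputed from beta and p, and flagged", {
  f <- tempfile(fileext = ".tsv")
  b <- 0.1; p <- 0.004
  writeLines(c("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tP\tN",
               sprintf("rs1\t1\t100\tA\tG\t0.3\t%g\t%g\t1000", b, p)), f)
  got <- read_sumstats(f)
  expect_true(got$se_imputed[1])
  expect_equal(got$se[1], abs(b) / qnorm(1 - p / 2))
})

test_that("allele swap flips outcome sign and allele frequency", {
  e <- make_records(beta = 0.10, se = 0.01, ea = "A", oa = "G")
  o <- make_records(beta = -0.05, se = 0.01, ea = "G", oa = "A", eaf = 0.7)
  hs <- harmonize(e, o)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$beta_out, 0.05)
  expect_equal(hs$eaf_out, 0.3)
  expect_true(hs$flipped_out)
})

test_that("palindromic SNPs are removed unconditionally", {
  e <- make_records(beta = c(0.1, 0.2), se = 0.01,
                    ea = c("A", "C"), oa = c("T", "G"))
  o <- make_records(beta = c(0.1, 0.2), se = 0.01,
                    ea = c("A", "C"), oa = c("T", "G"))
  hs <- harmonize(e, o)
  expect_equal(nrow(hs), 0)
  rep <- attr(hs, "report")
  expect_setequal(rep$snp[rep$reason == "palindromic"], c("rs1", "rs2"))
})

test_that("irreconcilable allele pairs are removed and counted", {
  e <- make_records(beta = c(0.1, 0.2), se = 0.01, ea = "A", oa = "G")
  o <- make_records(beta = c(0.1, 0.2), se = 0.01,
                    ea = c("A", "A"), oa = c("G", "C"))
  hs <- harmonize(e, o)
  expect_equal(nrow(hs), 1)
  rep <- attr(hs, "report")
  expect_equal(rep$snp[rep$reason == "irreconcilable_alleles"], "rs2")
})

test_that("strand-complement alleles are reconciled and flagged", {
  e <- make_records(beta = 0.1, se = 0.01, ea = "A", oa = "G")
  o_same <- make_records(beta = 0.07, se = 0.01, ea = "T", oa = "C")
  hs <- harmonize(e, o_same)
  expect_equal(hs$beta_out, 0.07)
  expect_true(hs$strand_out)
  o_swap <- make_records(beta = 0.07, se = 0.01, ea = "C", oa = "T")
  hs2 <- harmonize(e, o_swap)
  expect_equal(hs2$beta_out, -0.07)
})

test_that("empty SNP intersection warns and returns an empty set", {
  e <- make_records(beta = 0.1, se = 0.01, snp = "rsA")
  o <- make_records(beta = 0.1, se = 0.01, snp = "rsB")
  expect_warning(hs <- harmonize(e, o), "no SNPs shared")
  expect_equal(nrow(hs), 0)
})

test_that("harmonization is idempotent and invariant to outcome allele flips", {
  set.seed(42)
  n <- 30
  ea <- sample(c("A", "C"), n, TRUE)
  oa <- ifelse(ea == "A", "G", "T")  # never palindromic
  e <- make_records(beta = rnorm(n, 0, 0.05), se = runif(n, 0.005, 0.02),
                    ea = ea, oa = oa)
  o <- make_records(beta = rnorm(n, 0, 0.05), se = runif(n, 0.01, 0.03),
                    ea = ea, oa = oa, eaf = runif(n, 0.1, 0.9))
  hs1 <- harmonize(e, o)
  # feed the aligned outcome back through: nothing changes
  o_aligned <- o
  o_aligned$beta <- hs1$beta_out[match(o$snp, hs1$snp)]
  o_aligned$eaf <- hs1$eaf_out[match(o$snp, hs1$snp)]
  hs2 <- harmonize(e, o_aligned)
  expect_equal(hs2$beta_out, hs1$beta_out)
  expect_equal(hs2$eaf_out, hs1$eaf_out)
  # flipping alleles and negating beta pre-harmonization changes nothing
  o_flip <- o
  flip <- seq(1, n, by = 3)
  o_flip$ea[flip] <- o$oa[flip]; o_flip$oa[flip] <- o$ea[flip]
  o_flip$beta[flip] <- -o$beta[flip]; o_flip$eaf[flip] <- 1 - o$eaf[flip]
  hs3 <- harmonize(e, o_flip)
  expect_equal(hs3$beta_out, hs1$beta_out)
  expect_equal(hs3$eaf_out, hs1$eaf_out)
})

test_that("overlapping variant maps to the gene body with distance 0", {
  genes <- data.frame(gene_id = "GENE1", chr = "1", start = 100L, end = 200L)
  hit <- nearest_gene("1", 150, genes)
  expect_equal(hit$gene_id, "GENE1")
  expect_equal(hit$distance, 0)
})

test_that("nearest gene minimises boundary distance with signed output", {
  genes <- data.frame(gene_id = c("A", "B"), chr = "1",
                      start = c(1000L, 60000L), end = c(50000L, 90000L))
  # 3 kb downstream of A's end, 5 kb upstream of B's start (pos 53000 in
  # 1-based terms vs A body ..50000 and B body 60001..)
  hit <- nearest_gene("1", 53000, genes)
  expect_equal(hit$gene_id, "A")
  expect_equal(hit$distance, 3000)
  up <- nearest_gene("1", 58001, genes)
  expect_equal(up$gene_id, "B")
  expect_lt(up$distance, 0)
})

test_that("distance ties break to the smaller start, then gene id", {
  genes <- data.frame(gene_id = c("Z", "Y"), chr = "1",
                      start = c(200L, 400L), end = c(251L, 450L))
  # pos 326 (1-based): 75 beyond Z end (251), 75 before Y start (401)
  hit <- nearest_gene("1", 326, genes)
  expect_equal(hit$gene_id, "Z")
  genes2 <- data.frame(gene_id = c("B", "A"), chr = "1",
                       start = c(200L, 200L), end = c(250L, 250L))
  expect_equal(nearest_gene("1", 300, genes2)$gene_id, "A")
})

test_that("unannotated chromosome yields an explicit unmapped result", {
  genes <- data.frame(gene_id = "G", chr = "1", start = 1L, end = 10L)
  hit <- nearest_gene("2", 100, genes)
  expect_true(is.na(hit$gene_id))
  expect_true(is.na(hit$distance))
})

test_that("nearest_gene agrees with an exhaustive scan on random instances", {
  set.seed(7)
  for (rep in 1:20) {
    ng <- sample(5:60, 1)
    start <- sort(sample.int(1e6, ng))
    genes <- data.frame(gene_id = paste0("g", seq_len(ng)),
                        chr = as.character(sample(1:3, ng, TRUE)),
                        start = start,
                        end = start + sample.int(5e4, ng))
    for (q in 1:20) {
      chrom <- as.character(sample(1:3, 1))
      pos <- sample.int(1.1e6, 1)
      expect_equal(nearest_gene(chrom, pos, genes)$gene_id,
                   brute_nearest(chrom, pos, genes))
    }
  }
})

test_that("BED round-trip and audit writer produce readable files", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tGENE1", "2\t5\t50\tGENE2"), f)
  genes <- read_bed(f)
  expect_equal(genes$gene_id, c("GENE1", "GENE2"))
  expect_equal(genes$start, c(100L, 5L))
  a <- tempfile(fileext = ".tsv")
  write_audit(data.frame(snp = "rs1", action = "removed",
                         reason = "palindromic"), a)
  expect_true(file.exists(a))
})
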