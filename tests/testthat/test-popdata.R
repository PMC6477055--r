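# Fragment containers, text fragment format, alignment decoding, VCF I/O.

test_that("fragment_matrix validates and normalizes fragments", {
  fm <- fragment_matrix("m", list(frag(c(3, 1), c(1, 0))), 4L)
  expect_equal(fm$fragments[[1]]$snps, c(1L, 3L))     # sorted
  expect_equal(fm$fragments[[1]]$alleles, c(0L, 1L))
  expect_error(fragment_matrix("m", list(frag(5, 1)), 4L), "out of range")
  # zero-SNP fragments dropped
  expect_length(fragment_matrix("m", list(frag(integer(0), integer(0))),
                                4L)$fragments, 0L)
})

test_that("fragment text file round-trips", {
  fms <- list(mother = fm_of("mother", 6L,
                             frag(c(1, 2, 4), c(0, 1, 1), eps = 0.001,
                                  id = "a"),
                             frag(c(5, 6), c(1, 0), eps = 0.01, id = "b")),
              kid = fm_of("kid", 6L, frag(3, 1, eps = 0.1, id = "c")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_fragment_file(fms, path)
  back <- read_fragment_file(path, n_snps = 6L)
  expect_named(back, c("mother", "kid"))
  expect_equal(back$mother$fragments[[1]]$snps, c(1L, 2L, 4L))
  expect_equal(back$mother$fragments[[1]]$alleles, c(0L, 1L, 1L))
  expect_equal(back$mother$fragments[[2]]$eps, rep(0.01, 2))
  # write -> read -> write is byte-stable (phred-quantized errors)
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_fragment_file(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

make_test_bam <- function(dir) {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  # reference: SNPs at pos 5 (A/G), 15 (C/T), 25 (G/A)
  q30 <- rawToChar(as.raw(63))  # '?' = Q30
  rd <- function(qname, flag, pos, seq, qual)
    paste(qname, flag, "chr1", pos, 60, paste0(nchar(seq), "M"), "*", 0, 0,
          seq, qual, sep = "\t")
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:60",
    # template t1: mate1 covers SNP1 (A = ref), mate2 covers SNP3 (A = alt)
    rd("t1", 65, 1, "TTTTATTTTT", strrep(q30, 10)),
    rd("t1", 129, 21, "TTTTATTTTT", strrep(q30, 10)),
    # t2: single read, base at SNP2 is a third nucleotide (G, neither C nor T)
    rd("t2", 0, 11, "TTTTGTTTTT", strrep(q30, 10)),
    # t3: overlapping mates disagreeing at SNP2 -> site dropped
    rd("t3", 65, 11, "TTTTCTTTTT", strrep(q30, 10)),
    rd("t3", 129, 11, "TTTTTTTTTT", strrep(q30, 10)),
    # t4: base below the quality threshold at SNP1 (Q5 = '&')
    rd("t4", 0, 1, "TTTTGTTTTT", paste0(strrep(q30, 4), "&", strrep(q30, 5))),
    # t5: read covering no SNP -> fragment dropped
    rd("t5", 0, 31, "TTTTTTTTTT", strrep(q30, 10)))
  sam_path <- file.path(dir, "toy.sam")
  writeLines(sam, sam_path)
  Rsamtools::asBam(sam_path, file.path(dir, "toy"), overwrite = TRUE,
                   indexDestination = TRUE)
}

test_that("alignment decoding: allele coding, mate merge, conflicts, quality", {
  dir <- withr::local_tempdir()
  bam <- make_test_bam(dir)
  sites <- data.frame(chrom = "chr1", pos = c(5L, 15L, 25L),
                      ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  fm <- read_fragments(bam, sites, individual = "m")
  ids <- vapply(fm$fragments, `[[`, character(1), "id")
  # t1: mates merged into one fragment covering SNPs 1 and 3
  t1 <- fm$fragments[[which(ids == "t1")]]
  expect_equal(t1$snps, c(1L, 3L))
  expect_equal(t1$alleles, c(0L, 1L))     # ref at SNP1, alt at SNP3
  expect_equal(t1$eps, rep(1e-3, 2))      # Q30 -> 0.001
  # t2: third nucleotide leaves the SNP uncovered -> fragment dropped
  expect_false("t2" %in% ids)
  # t3: mate conflict at SNP2 drops the site -> no covered SNP left
  expect_false("t3" %in% ids)
  # t4: low-quality base excluded
  expect_false("t4" %in% ids)
  # t5: no SNP covered
  expect_false("t5" %in% ids)
  # determinism
  fm2 <- read_fragments(bam, sites, individual = "m")
  expect_identical(fm, fm2)
})

test_that("phased VCF writing and reading round-trip a simulated population", {
  sim <- quick_sim(n_offspring = 3L, seed = 29L)
  fit <- phase_population(sim)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(path, sim$sites, fit$genotypes, fit$phasings,
                   ploidy = sim$ploidy, original_genotypes = sim$genotypes)
  back <- read_population_vcf(path)
  expect_equal(back$sites$pos, sim$sites$pos)
  expect_equal(unname(back$ploidy), rep(4L, length(sim$individuals)))
  expect_equal(back$genotypes[rownames(fit$genotypes), ], fit$genotypes,
               ignore_attr = TRUE)
  # phase sets: per individual, phased site sets and block partition survive
  for (ind in sim$individuals) {
    want_sites <- lapply(fit$phasings[[ind]], `[[`, "sites")
    got_sites <- lapply(back$phasings[[ind]], `[[`, "sites")
    expect_setequal(vapply(got_sites, paste, "", collapse = ","),
                    vapply(want_sites, paste, "", collapse = ","))
    # ordered GT columns round-trip exactly
    for (blk in fit$phasings[[ind]]) {
      hit <- Filter(function(b) identical(b$sites, blk$sites),
                    back$phasings[[ind]])
      expect_length(hit, 1L)
      expect_equal(hit[[1]]$H, blk$H, ignore_attr = TRUE)
    }
  }
})

test_that("unphased and phased GT encodings are written as specified", {
  sites <- data.frame(chrom = "c", pos = c(10L, 20L), ref = c("A", "C"),
                      alt = c("T", "G"))
  G <- rbind(ind1 = c(2L, 1L), ind2 = c(NA, 4L))
  ph <- list(ind1 = list(list(sites = 1:2,
                              H = rbind(c(0L, 0L), c(0L, 0L),
                                        c(1L, 0L), c(1L, 1L)))))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(path, sites, G, ph)
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  f1 <- strsplit(lines[1], "\t")[[1]]
  expect_equal(f1[10], "0|0|1|1:10")       # phased, PS = first block pos
  expect_equal(f1[11], "./././.:.")        # missing dosage
  f2 <- strsplit(lines[2], "\t")[[1]]
  expect_equal(f2[10], "0|0|0|1:10")
  expect_equal(f2[11], "1/1/1/1:.")        # unphased dosage 4
  # dosage/phasing mismatch is a hard error
  G_bad <- G; G_bad["ind1", 1] <- 3L
  expect_error(write_phased_vcf(path, sites, G_bad, ph), "mismatch")
})

test_that("multi-allelic and non-SNP records are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "c\t5\t.\tA\tT\t.\tPASS\t.\tGT\t0/0/0/1",
    "c\t9\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/0/1/2",
    "c\t12\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0/0/0"), path)
  expect_warning(v <- read_population_vcf(path), "skipped")
  expect_equal(v$sites$pos, 5L)
  expect_equal(unname(v$genotypes[1, 1]), 1L)
})

test_that("block partition exports as a BED-like table", {
  sites <- data.frame(chrom = "c", pos = c(10L, 20L, 400L), ref = "A",
                      alt = "T")
  part <- find_blocks(fm_of("m", 3L, frag(1:2, c(0, 1))), 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_block_table(part, sites, path)
  expect_equal(tab$start, c(9L, 399L))
  expect_equal(tab$end, c(20L, 400L))
  expect_equal(tab$n_snps, c(2L, 1L))
  expect_true(file.exists(path))
})
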