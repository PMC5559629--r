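# Hand-built QC fixture: 10 animals x 25 SNPs.
#  - animal an001 misses 2 calls of 25 (8% > 5% mind) -> removed at stage 1
#  - animal an002 misses 1 call of 25 (4% <= 5%) -> kept
#  - SNP s0001 (an002's missing call) is missing in 1 of the 9 remaining
#    animals (11% > 5% geno) -> removed at stage 2
#  - SNP s0002 is monomorphic among the remaining animals (MAF 0)
#  - SNP s0003 has exactly 1 minor allele in 9 animals (MAF 1/18 = 5.6%) kept
qc_fixture <- function() {
  n <- 10L; m <- 25L
  calls <- matrix(1L, n, m)
  set.seed(8)
  calls[, 4:m] <- sample(0:2, n * (m - 3L), replace = TRUE)
  calls[1, 4:5] <- NA            # an001: 2/25 missing -> mind removal
  calls[2, 1] <- NA              # s0001: 1/9 missing after an001 leaves
  calls[, 2] <- 2L               # s0002 monomorphic
  calls[, 3] <- 0L; calls[2, 3] <- 1L   # s0003: MAF 1/18 among an002..an010
  genotype_matrix(
    calls,
    fam = data.frame(fid = "f0", iid = sprintf("an%03d", 1:n), pat = "0",
                     mat = "0", sex = "0", pheno = "-9"),
    map = data.frame(chr = "1", snp = sprintf("s%04d", 1:m), cm = 0,
                     bp = 1:m))
}
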