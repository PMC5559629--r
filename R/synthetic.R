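#' Half-sib herd design
#'
#' Describes the cohort the genotype generator emulates: a herd in which a
#' genotyped subset is structured as paternal half-sib families (groups
#' sharing a common sire) and the remaining animals are unrelated. The
#' default mirrors the study herd: 78 animals, 47 genotyped, 11 sire groups
#' of sizes 4, 3 and nine pairs.
#'
#' @param n_animals total cohort size.
#' @param n_genotyped number of genotyped animals (first `n_genotyped` ids).
#' @param families integer vector of offspring counts, one per sire group;
#'   must sum to at most `n_genotyped`.
#' @param n_snps number of independent biallelic SNPs.
#' @param maf_range allele-frequency bounds in `(0, 0.5]` from which each
#'   SNP's reference-allele frequency is drawn.
#' @param missing_rate probability that any single call is missing.
#' @param seed integer seed.
#' @return An object of class `herd_design`.
#' @export
herd_design <- function(n_animals = 78L, n_genotyped = 47L,
                        families = c(4L, 3L, rep(2L, 9L)),
                        n_snps = 40000L, maf_range = c(0.05, 0.5),
                        missing_rate = 0.01, seed = 1L) {
  if (n_genotyped > n_animals) stop("n_genotyped must be <= n_animals")
  families <- as.integer(families)
  if (any(families < 2L)) stop("each sire family needs >= 2 offspring")
  if (sum(families) > n_genotyped)
    stop("family offspring counts exceed the genotyped subset (",
         sum(families), " > ", n_genotyped, ")")
  if (length(maf_range) != 2L || maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L])
    stop("maf_range bounds must satisfy 0 < low <= high <= 0.5")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(list(n_animals = as.integer(n_animals),
                 n_genotyped = as.integer(n_genotyped),
                 families = families, n_snps = as.integer(n_snps),
                 maf_range = maf_range, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "herd_design")
}

#' Simulate half-sib genotypes and the pedigree relatedness they imply
#'
#' Each SNP's reference-allele frequency is drawn uniformly from
#' `maf_range`. For a sire family, two sire haplotypes are drawn from the
#' population frequencies and every offspring inherits one randomly chosen
#' sire allele per SNP plus a fresh maternal allele, giving the pedigree
#' expectation of 0.25 relatedness between half-sibs without full pedigree
#' machinery. Animals outside families draw both alleles independently.
#' SNPs are independent (no linkage).
#'
#' @param design a [herd_design()].
#' @return A list with `genotypes` (a [genotype_matrix()] over the genotyped
#'   subset) and `pedigree` (a [relatedness_matrix()] over the full cohort:
#'   1 on the diagonal, 0.25 between half-sibs, 0 elsewhere).
#' @export
simulate_genotypes <- function(design) {
  stopifnot(inherits(design, "herd_design"))
  set.seed(design$seed)
  n <- design$n_animals
  ng <- design$n_genotyped
  m <- design$n_snps
  ids <- sprintf("cow%03d", seq_len(n))
  gen_ids <- ids[seq_len(ng)]

  fam_sizes <- design$families
  fam_of <- rep(NA_integer_, ng)
  if (length(fam_sizes)) {
    assign <- rep(seq_along(fam_sizes), fam_sizes)
    fam_of[seq_along(assign)] <- assign
  }
  fid <- ifelse(is.na(fam_of), sprintf("unr%03d", seq_len(ng)),
                sprintf("sire%02d", fam_of))

  p <- runif(m, design$maf_range[1L], design$maf_range[2L])
  calls <- matrix(0L, ng, m)
  for (f in seq_along(fam_sizes)) {
    members <- which(!is.na(fam_of) & fam_of == f)
    hap1 <- rbinom(m, 1L, p)
    hap2 <- rbinom(m, 1L, p)
    for (a in members) {
      pick <- rbinom(m, 1L, 0.5)
      sire_allele <- ifelse(pick == 1L, hap1, hap2)
      calls[a, ] <- sire_allele + rbinom(m, 1L, p)
    }
  }
  singles <- which(is.na(fam_of))
  for (a in singles) calls[a, ] <- rbinom(m, 2L, p)
  if (design$missing_rate > 0) {
    miss <- matrix(runif(ng * m) < design$missing_rate, ng, m)
    calls[miss] <- NA_integer_
  }

  chr <- rep(seq_len(29L), length.out = m)
  o <- order(chr)
  map <- data.frame(chr = as.character(chr[o]),
                    snp = sprintf("snp%05d", seq_len(m)),
                    cm = 0, bp = as.numeric(ave(seq_len(m), chr[o],
                                                FUN = seq_along) * 1000),
                    stringsAsFactors = FALSE)
  fam <- data.frame(fid = fid, iid = gen_ids, pat = "0", mat = "0",
                    sex = "0", pheno = "-9", stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, fam, map)

  A <- matrix(0, n, n)
  for (f in seq_along(fam_sizes)) {
    members <- which(!is.na(fam_of) & fam_of == f)
    A[members, members] <- 0.25
  }
  diag(A) <- 1
  ped_ids <- data.frame(fid = c(fid, sprintf("ung%03d", seq_len(n - ng))),
                        iid = ids, stringsAsFactors = FALSE)
  list(genotypes = g,
       pedigree = relatedness_matrix(A, ped_ids, max(m, 1L)))
}

.taxonomy_pool <- list(
  Bacteroidales   = c("Bacteria", "Bacteroidetes", "Bacteroidia",
                      "Bacteroidales", "Prevotellaceae", "Prevotella"),
  Clostridiales   = c("Bacteria", "Firmicutes", "Clostridia",
                      "Clostridiales", "Ruminococcaceae", "Ruminococcus"),
  Fibrobacterales = c("Bacteria", "Fibrobacteres", "Fibrobacteria",
                      "Fibrobacterales", "Fibrobacteraceae", "Fibrobacter"),
  Spirochaetales  = c("Bacteria", "Spirochaetes", "Spirochaetia",
                      "Spirochaetales", "Spirochaetaceae", "Treponema"),
  Selenomonadales = c("Bacteria", "Firmicutes", "Negativicutes",
                      "Selenomonadales", "Veillonellaceae", "Selenomonas")
)

#' Planted-microbiome specification
#'
#' Describes the synthetic OTU community: which OTUs carry a genetically
#' driven abundance component (and how much), how prevalent each OTU is
#' across animals, and how tight the 16S clade formed by the heritable
#' subset is relative to the background. Taxonomy lineages are drawn here so
#' the abundance table and the sequence set share them; the heritable clade
#' is enriched for one order (Bacteroidales), as the screen's enrichment
#' test expects to be able to detect.
#'
#' @param n_otus number of OTUs.
#' @param n_days sampling days per animal (3, matching three consecutive
#'   daily samples).
#' @param n_heritable number of OTUs given a genetic component (ignored when
#'   `heritable_ids` is supplied).
#' @param heritable_ids optional explicit OTU ids to plant.
#' @param true_h2 heritability of each planted OTU's latent, in `[0, 1]`;
#'   scalar or one value per heritable OTU.
#' @param presence_profile per-OTU fraction of animals carrying the OTU;
#'   `NULL` draws heritable OTUs in `[0.7, 1]` (heritable taxa are highly
#'   prevalent in the rumen) and background OTUs in `[0.1, 1]`.
#' @param clade_identity expected pairwise sequence identity fraction within
#'   the heritable clade; must exceed `background_identity`.
#' @param background_identity expected identity fraction among background
#'   OTUs.
#' @param day_noise_frac standard deviation of the day-to-day latent noise
#'   as a fraction of the total latent standard deviation (shared genetic
#'   plus animal-level environment make up the rest), so the three daily
#'   replicates are consistent enough for a three-day consensus call.
#' @param clade_order_prob probability that a heritable-clade OTU is
#'   labelled with the enriched order.
#' @param seed integer seed (used for the draws made here and, by default,
#'   to derive the seeds of the generators that consume this spec).
#' @return An object of class `planted_microbiome`.
#' @export
planted_microbiome <- function(n_otus = 500L, n_days = 3L,
                               n_heritable = 10L, heritable_ids = NULL,
                               true_h2 = 0.85, presence_profile = NULL,
                               clade_identity = 0.90,
                               background_identity = 0.75,
                               day_noise_frac = 0.2,
                               clade_order_prob = 0.8, seed = 1L) {
  n_otus <- as.integer(n_otus)
  otu_ids <- sprintf("otu%05d", seq_len(n_otus))
  set.seed(seed)
  if (is.null(heritable_ids)) {
    n_heritable <- as.integer(n_heritable)
    heritable_ids <- sort(sample(otu_ids, n_heritable))
  } else {
    if (!all(heritable_ids %in% otu_ids))
      stop("heritable_ids must be drawn from the generated OTU ids")
    heritable_ids <- sort(unique(heritable_ids))
  }
  if (any(true_h2 < 0 | true_h2 > 1)) stop("true_h2 must lie in [0, 1]")
  true_h2 <- rep_len(true_h2, length(heritable_ids))
  if (clade_identity <= background_identity)
    stop("clade_identity must exceed background_identity")
  if (is.null(presence_profile)) {
    presence_profile <- runif(n_otus, 0.1, 1)
    presence_profile[otu_ids %in% heritable_ids] <-
      runif(length(heritable_ids), 0.7, 1)
  }
  presence_profile <- rep_len(presence_profile, n_otus)
  if (any(presence_profile <= 0 | presence_profile > 1))
    stop("presence_profile fractions must lie in (0, 1]")

  orders <- names(.taxonomy_pool)
  is_her <- otu_ids %in% heritable_ids
  ord <- sample(orders, n_otus, replace = TRUE,
                prob = c(0.35, 0.35, 0.1, 0.1, 0.1))
  clade_ord <- ifelse(runif(sum(is_her)) < clade_order_prob,
                      "Bacteroidales",
                      sample(orders, sum(is_her), replace = TRUE))
  ord[is_her] <- clade_ord
  taxonomy <- vapply(ord, function(o) paste(.taxonomy_pool[[o]],
                                            collapse = ";"), "")
  names(taxonomy) <- otu_ids

  structure(list(n_otus = n_otus, n_days = as.integer(n_days),
                 otu_ids = otu_ids, heritable_ids = heritable_ids,
                 true_h2 = setNames(true_h2, heritable_ids),
                 presence_profile = setNames(presence_profile, otu_ids),
                 clade_identity = clade_identity,
                 background_identity = background_identity,
                 day_noise_frac = day_noise_frac,
                 taxonomy = taxonomy, seed = as.integer(seed)),
            class = "planted_microbiome")
}

#' Simulate an OTU relative-abundance table with a planted genetic signal
#'
#' Each OTU gets a latent value per animal and day. For a heritable OTU the
#' latent is `g + e_animal + e_day` with `g` drawn zero-mean with covariance
#' `true_h2 * A` (through the supplied relatedness matrix), the day noise
#' variance fixed by `day_noise_frac`, and the animal-level environmental
#' variance filling the remainder so the per-day latent heritability equals
#' `true_h2` exactly; the genetic and animal components are shared across
#' the three daily replicates. Non-heritable OTUs take pure-noise latents.
#' Latents are mapped through the exponential (log-normal abundances),
#' animals with the lowest day-invariant latent are zeroed until the OTU's
#' presence fraction is met, and each (animal, day) sample is renormalized
#' to sum to one.
#'
#' The latent scale is kept deliberately modest (`latent_sd`) so that the
#' strictly monotone exponential map distorts the variance decomposition
#' only mildly and the planted heritability survives onto the observed
#' relative-abundance scale.
#'
#' @param grm a [relatedness_matrix()] covering the animals to simulate.
#'   Use the realized GRM of the genotyped animals (optionally embedded in
#'   the full cohort via [embed_relatedness()]) so that the planted genetic
#'   covariance is exactly the one the downstream REML fits see; planting
#'   through the pedigree expectation instead leaves a generating-model
#'   mismatch that attenuates recovered heritability.
#' @param spec a [planted_microbiome()].
#' @param latent_sd total standard deviation of each OTU's latent.
#' @param baseline_log_sd spread of per-OTU log baseline abundances.
#' @param seed integer seed; defaults to `spec$seed + 1` so the spec's own
#'   draws are not replayed.
#' @return An [abundance_table()].
#' @export
simulate_abundances <- function(grm, spec, latent_sd = 0.2,
                                baseline_log_sd = 0.5,
                                seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "planted_microbiome"))
  if (!inherits(grm, "relatedness_matrix"))
    stop("grm must be a relatedness_matrix")
  A <- grm$A
  if (max(abs(A - t(A))) > 1e-8) stop("relationship matrix is not symmetric")
  e <- eigen(A, symmetric = TRUE)
  if (max(e$values) <= 0)
    stop("relationship matrix is degenerate (no positive eigenvalues)")
  if (min(e$values) < -0.05 * mean(diag(A)))
    stop("relationship matrix is not positive semidefinite")
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(A))
  animals <- as.character(grm$ids$iid)
  n <- length(animals)
  n_otus <- spec$n_otus
  n_days <- spec$n_days

  set.seed(seed)
  mu <- rnorm(n_otus, 0, baseline_log_sd)
  h2 <- setNames(numeric(n_otus), spec$otu_ids)
  h2[names(spec$true_h2)] <- spec$true_h2
  day_var <- pmin(spec$day_noise_frac^2, 1 - h2)
  env_var <- pmax(1 - h2 - day_var, 0)

  G <- (L %*% matrix(rnorm(n * n_otus), n, n_otus)) *
    rep(sqrt(h2), each = n)
  Ea <- matrix(rnorm(n * n_otus), n, n_otus) * rep(sqrt(env_var), each = n)
  stable <- G + Ea  # day-invariant part of each latent

  values <- matrix(0, n_otus, n * n_days)
  sample_animal <- rep(animals, times = n_days)
  sample_day <- rep(seq_len(n_days), each = n)
  colnames(values) <- paste0(sample_animal, "_d", sample_day)

  keep_mask <- matrix(TRUE, n, n_otus)
  n_zero <- round((1 - spec$presence_profile) * n)
  for (o in seq_len(n_otus)) {
    if (n_zero[o] > 0L)
      keep_mask[order(stable[, o])[seq_len(n_zero[o])], o] <- FALSE
  }

  for (d in seq_len(n_days)) {
    Ed <- matrix(rnorm(n * n_otus), n, n_otus) * rep(sqrt(day_var), each = n)
    latent <- sweep((stable + Ed) * latent_sd, 2L, mu, `+`)
    ab <- exp(latent) * keep_mask
    values[, sample_day == d] <- t(ab)
  }
  tot <- colSums(values)
  if (any(tot == 0)) stop("a sample ended up with no nonzero OTUs")
  values <- sweep(values, 2L, tot, `/`)

  abundance_table(values,
                  otus = data.frame(otu_id = spec$otu_ids,
                                    taxonomy = unname(spec$taxonomy),
                                    stringsAsFactors = FALSE),
                  samples = data.frame(sample_id = colnames(values),
                                       animal = sample_animal,
                                       day = sample_day,
                                       stringsAsFactors = FALSE))
}

# per-site substitution probability giving an expected pairwise identity c
# between two descendants of a shared ancestor: (1-q)^2 + q^2/3 = c
.identity_to_rate <- function(c) {
  disc <- 1 - (4 / 3) * (1 - c)
  if (disc < 0) stop("target identity ", c, " is unreachable")
  0.75 * (1 - sqrt(disc))
}

.mutate_seq <- function(chars, q) {
  hit <- runif(length(chars)) < q
  if (any(hit)) {
    alts <- c("A", "C", "G", "T")
    repl <- vapply(chars[hit],
                   function(b) sample(setdiff(alts, b), 1L), "")
    chars[hit] <- repl
  }
  chars
}

#' Simulate 16S-like sequences with a planted tight clade
#'
#' One nucleotide sequence per OTU under a star topology: background OTUs
#' are independent descendants of a global ancestor with the substitution
#' rate tuned so their expected pairwise identity equals
#' `background_identity`; the heritable OTUs instead descend from a single
#' clade ancestor (itself a background descendant) with a lower rate tuned
#' to `clade_identity`, so the heritable subset forms a tight clade.
#'
#' @param spec a [planted_microbiome()].
#' @param seq_length sequence length in nucleotides.
#' @param seed integer seed; defaults to `spec$seed + 2`.
#' @return A [sequence_set()] carrying the spec's taxonomy.
#' @export
simulate_sequences <- function(spec, seq_length = 250L,
                               seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "planted_microbiome"))
  if (spec$clade_identity <= spec$background_identity)
    stop("clade_identity must exceed background_identity")
  set.seed(seed)
  q_back <- .identity_to_rate(spec$background_identity)
  q_clade <- .identity_to_rate(spec$clade_identity)
  ancestor <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE)
  clade_anc <- .mutate_seq(ancestor, q_back)
  seqs <- character(spec$n_otus)
  is_her <- spec$otu_ids %in% spec$heritable_ids
  for (o in seq_len(spec$n_otus)) {
    seqs[o] <- paste(
      if (is_her[o]) .mutate_seq(clade_anc, q_clade)
      else .mutate_seq(ancestor, q_back),
      collapse = "")
  }
  sequence_set(setNames(seqs, spec$otu_ids), taxonomy = spec$taxonomy)
}

#' Embed a genotyped-subset relatedness matrix in a full cohort
#'
#' Returns a cohort-level relatedness matrix whose genotyped block is the
#' supplied (realized) GRM; animals outside the genotyped subset are taken
#' as unrelated (diagonal 1, zero off-diagonals). This lets the abundance
#' generator cover the whole cohort while planting the genetic signal
#' through exactly the matrix the heritability fits will use.
#'
#' @param grm a [relatedness_matrix()] over the genotyped animals.
#' @param cohort_ids ids of all animals (must contain the GRM's ids).
#' @return A [relatedness_matrix()] over `cohort_ids`.
#' @export
embed_relatedness <- function(grm, cohort_ids) {
  stopifnot(inherits(grm, "relatedness_matrix"))
  cohort_ids <- as.character(cohort_ids)
  gen <- as.character(grm$ids$iid)
  if (!all(gen %in% cohort_ids))
    stop("cohort_ids must contain every genotyped animal")
  n <- length(cohort_ids)
  A <- diag(1, n)
  idx <- match(gen, cohort_ids)
  A[idx, idx] <- grm$A
  np <- matrix(max(grm$n_pairs), n, n)
  np[idx, idx] <- grm$n_pairs
  fid <- rep("cohort", n)
  fid[idx] <- grm$ids$fid
  relatedness_matrix(A, data.frame(fid = fid, iid = cohort_ids,
                                   stringsAsFactors = FALSE), np)
}

#' Trait linkage specification
#'
#' Describes how synthetic host/rumen indices are tied to OTU abundances:
#' each index is a weighted sum of mean-across-days abundances of its linked
#' OTUs plus Gaussian noise.
#'
#' @param links named list, one entry per index; each entry is a named
#'   numeric vector of signed effect weights keyed by OTU id.
#' @param noise_sd positive noise standard deviation, scalar or one per
#'   index.
#' @param categories optional character vector of category labels (amino
#'   acid, sugar, VFA, physiological, ...) parallel to `links`.
#' @param seed integer seed.
#' @return An object of class `trait_linkage`.
#' @export
trait_linkage <- function(links, noise_sd, categories = NULL, seed = 1L) {
  if (is.null(names(links)) || any(!nzchar(names(links))))
    stop("every index needs a name")
  if (any(noise_sd <= 0)) stop("noise sd must be positive")
  noise_sd <- rep_len(noise_sd, length(links))
  if (is.null(categories)) categories <- rep("other", length(links))
  structure(list(links = links,
                 noise_sd = setNames(noise_sd, names(links)),
                 categories = setNames(rep_len(categories, length(links)),
                                       names(links)),
                 seed = as.integer(seed)),
            class = "trait_linkage")
}

#' Simulate a trait/metabolite table linked to OTU abundances
#'
#' @param abund an [abundance_table()].
#' @param linkage a [trait_linkage()]; every linked OTU id must exist in the
#'   table.
#' @return A data frame with column `animal` followed by one numeric column
#'   per index, with the linkage categories attached as attribute
#'   `categories`.
#' @export
simulate_traits <- function(abund, linkage) {
  stopifnot(inherits(abund, "abundance_table"),
            inherits(linkage, "trait_linkage"))
  M <- animal_abundance(abund)
  set.seed(linkage$seed)
  out <- data.frame(animal = colnames(M), stringsAsFactors = FALSE)
  for (idx in names(linkage$links)) {
    wts <- linkage$links[[idx]]
    missing_otus <- setdiff(names(wts), rownames(M))
    if (length(missing_otus))
      stop("index ", idx, " links unknown OTU id(s): ",
           paste(missing_otus, collapse = ", "))
    signal <- as.numeric(crossprod(M[names(wts), , drop = FALSE], wts))
    out[[idx]] <- signal + rnorm(ncol(M), 0, linkage$noise_sd[[idx]])
  }
  attr(out, "categories") <- linkage$categories
  out
}

#' Build an example trait linkage from planted heritable OTUs
#'
#' Constructs a small panel of named indices (VFA-like ratios, metabolites,
#' physiological measures), each linked to a few heritable OTUs with signed
#' weights scaled to the table's abundance range, and sets the noise so the
#' deterministic part dominates at roughly the requested signal-to-noise
#' ratio.
#'
#' @param abund an [abundance_table()].
#' @param heritable_ids OTU ids to link.
#' @param n_indices number of indices (capped at 8 named ones).
#' @param snr ratio of signal sd to noise sd.
#' @param seed integer seed.
#' @return A [trait_linkage()].
#' @export
example_trait_linkage <- function(abund, heritable_ids, n_indices = 8L,
                                  snr = 2, seed = 1L) {
  panel <- c(propionate_acetate_ratio = "VFA", methane = "other_metabolite",
             propionate = "VFA", valerate = "VFA", glycine = "amino_acid",
             glucose = "sugar", milk_protein = "physiological",
             dry_matter_intake = "physiological")
  n_indices <- min(n_indices, length(panel))
  idx_names <- names(panel)[seq_len(n_indices)]
  set.seed(seed)
  M <- animal_abundance(abund)
  links <- list(); noise <- numeric(n_indices)
  for (i in seq_len(n_indices)) {
    k <- min(length(heritable_ids), sample(2:4, 1L))
    otus <- sample(heritable_ids, k)
    wts <- setNames(sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.5, 1.5),
                    otus)
    signal <- as.numeric(crossprod(M[otus, , drop = FALSE], wts))
    s <- sd(signal)
    if (s == 0) s <- 1
    links[[idx_names[i]]] <- wts
    noise[i] <- s / snr
  }
  trait_linkage(links, noise, categories = unname(panel[idx_names]),
                seed = seed + 1L)
}

#' Write the ground truth of a planted microbiome
#'
#' TSV with one row per OTU: `otu_id`, `true_h2`, `clade` flag and the
#' presence fraction used by the generator.
#'
#' @param spec a [planted_microbiome()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(spec, path) {
  df <- data.frame(
    otu_id = spec$otu_ids,
    true_h2 = ifelse(spec$otu_ids %in% names(spec$true_h2),
                     spec$true_h2[spec$otu_ids], 0),
    clade = spec$otu_ids %in% spec$heritable_ids,
    presence = unname(spec$presence_profile))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
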