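#' Configuration for the synthetic MPRA read generator
#'
#' Defaults describe a small but realistic enhancer-screen regime: 200
#' designed oligos of 100 nt, ~15 random 12-nt barcodes each, half a
#' million DNA and RNA counting reads, Illumina-like substitution error
#' 0.001/base. True activities are lognormal with a 1 log2-unit spread;
#' barcode representation is skewed lognormally (0.5 log2 units), as
#' cloning bottlenecks produce in practice.
#'
#' @param n_oligos Number of designed oligos.
#' @param oligo_len Oligo length, nt.
#' @param barcode_len Barcode length, nt (>= 6).
#' @param mean_barcodes_per_oligo Poisson mean (floored at 1 per oligo).
#' @param activity_log2_sd SD of true log2 activities.
#' @param abundance_log2_sd SD of log2 barcode abundance skew.
#' @param reads_step1 Association-mapping read pairs.
#' @param reads_dna,reads_rna Counting reads per replicate.
#' @param read_len Read length for the paired association run, nt.
#' @param error_rate Per-base substitution probability, in [0, 0.1].
#' @param n_replicates Replicates for the counting stages.
#' @param seed Master seed; all emissions derive sub-seeds from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_oligos = 200L, oligo_len = 100L, barcode_len = 12L,
                       mean_barcodes_per_oligo = 15,
                       activity_log2_sd = 1, abundance_log2_sd = 0.5,
                       reads_step1 = 200000L, reads_dna = 500000L,
                       reads_rna = 500000L, read_len = 75L,
                       error_rate = 0.001, n_replicates = 2L, seed = 7L) {
    cfg <- list(n_oligos = as.integer(n_oligos),
                oligo_len = as.integer(oligo_len),
                barcode_len = as.integer(barcode_len),
                mean_barcodes_per_oligo = mean_barcodes_per_oligo,
                activity_log2_sd = activity_log2_sd,
                abundance_log2_sd = abundance_log2_sd,
                reads_step1 = as.integer(reads_step1),
                reads_dna = as.integer(reads_dna),
                reads_rna = as.integer(reads_rna),
                read_len = as.integer(read_len),
                error_rate = error_rate,
                n_replicates = as.integer(n_replicates),
                seed = as.integer(seed))
    counts <- c(cfg$n_oligos, cfg$oligo_len, cfg$barcode_len,
                cfg$reads_step1, cfg$reads_dna, cfg$reads_rna,
                cfg$read_len, cfg$n_replicates)
    if (any(counts <= 0L)) stop("all counts and lengths must be > 0")
    if (cfg$barcode_len < 6L) stop("barcode_len must be >= 6")
    if (error_rate < 0 || error_rate > 0.1)
        stop("error_rate must be in [0, 0.1]")
    if (mean_barcodes_per_oligo <= 0) stop("mean_barcodes_per_oligo must be > 0")
    structure(cfg, class = "sim_config")
}

# The constant linker placed between oligo insert and barcode in the
# simulated construct (upstream flank of the barcode).
sim_flank_up <- function() "GCTAGC"

#' Read structures matching the simulated construct
#'
#' The simulated fragment is `oligo + linker + barcode` with the barcode
#' at the 3' end; counting reads are `linker + barcode`. Both steps
#' therefore share barcode length and flank.
#'
#' @param cfg A [sim_config()].
#' @param step `"map"` for merged association fragments, `"counts"` for
#'   the DNA/RNA counting reads.
#' @return A [read_structure()].
#' @export
default_read_structure <- function(cfg, step = c("map", "counts")) {
    step <- match.arg(step)
    read_structure(barcode_len = cfg$barcode_len,
                   barcode_end = "three_prime",
                   barcode_flank_up = sim_flank_up())
}

rand_seqs_ <- function(n, len) {
    stringi::stri_rand_strings(n, len, pattern = "[ACGT]")
}

# draw n unique random sequences of given length
unique_seqs_ <- function(n, len) {
    out <- unique(rand_seqs_(n, len))
    guard <- 0L
    while (length(out) < n) {
        out <- unique(c(out, rand_seqs_(n - length(out) + 10L, len)))
        guard <- guard + 1L
        if (guard > 100L) stop("could not draw enough unique sequences")
    }
    out[seq_len(n)]
}

#' Generate the ground-truth tables for a simulated MPRA experiment
#'
#' Draws unique random oligo sequences, a Poisson number of globally
#' unique barcodes per oligo, lognormal barcode abundances (normalized
#' to sum 1), and lognormal per-oligo true activities. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An `mpra_truth`: list with `oligos` (named sequences),
#'   `barcode_map` (data.frame `barcode`, `oligo_id`), `abundance`
#'   (named, sums to 1), `activity` (named by oligo), `cfg`.
#' @export
simulate_truth <- function(cfg) {
    with_seed_(cfg$seed, {
        n_bc_per <- pmax(1L, stats::rpois(cfg$n_oligos,
                                          cfg$mean_barcodes_per_oligo))
        total_bc <- sum(n_bc_per)
        if (cfg$barcode_len * log(4) < log(10 * total_bc))
            stop("barcode space too small: need 4^barcode_len >= ",
                 10 * total_bc)
        oligo_ids <- sprintf("oligo_%04d", seq_len(cfg$n_oligos))
        oligos <- stats::setNames(unique_seqs_(cfg$n_oligos, cfg$oligo_len),
                                  oligo_ids)
        barcodes <- unique_seqs_(total_bc, cfg$barcode_len)
        bc_map <- data.frame(barcode = barcodes,
                             oligo_id = rep(oligo_ids, n_bc_per),
                             stringsAsFactors = FALSE)
        ab <- stats::rlnorm(total_bc, 0, cfg$abundance_log2_sd * log(2))
        ab <- ab / sum(ab)
        act <- stats::rlnorm(cfg$n_oligos, 0, cfg$activity_log2_sd * log(2))
        structure(list(oligos = oligos, barcode_map = bc_map,
                       abundance = stats::setNames(ab, barcodes),
                       activity = stats::setNames(act, oligo_ids),
                       cfg = cfg),
                  class = "mpra_truth")
    })
}

# vectorized substitution errors at per-base rate e (uniform over the
# three other bases); all sequences must share one length
add_errors_ <- function(seqs, e) {
    if (e <= 0 || length(seqs) == 0L) return(seqs)
    L <- nchar(seqs[1])
    n <- length(seqs)
    bases <- c("A", "C", "G", "T")
    for (j in seq_len(L)) {
        hit <- which(stats::runif(n) < e)
        if (length(hit) == 0L) next
        cur <- substr(seqs[hit], j, j)
        # uniform over the three non-current bases via offset 1..3
        off <- sample.int(3L, length(hit), replace = TRUE)
        pos <- match(cur, bases)
        pos[is.na(pos)] <- 1L   # N or odd base: substitute from A
        repl <- bases[((pos - 1L + off) %% 4L) + 1L]
        substr(seqs[hit], j, j) <- repl
    }
    seqs
}

phred_string_ <- function(e, len) {
    q <- if (e <= 0) 40L else max(2L, min(40L, as.integer(round(-10 * log10(e)))))
    strrep(rawToChar(as.raw(q + 33L)), len)
}

#' Emit paired association-mapping reads (simulated step 1)
#'
#' Each fragment is `oligo + linker + barcode`; the barcode is drawn
#' proportionally to its true abundance. Forward and reverse reads of
#' `read_len` nt are cut from the fragment ends (reverse read
#' reverse-complemented), substitution errors applied independently,
#' and constant Phred qualities consistent with the error rate written.
#'
#' @param truth An `mpra_truth` from [simulate_truth()].
#' @param cfg The matching [sim_config()].
#' @param r1_path,r2_path Output FASTQ paths (`.gz` suffix gzips).
#' @return Invisibly, c(r1_path, r2_path).
#' @export
emit_step1_reads <- function(truth, cfg, r1_path, r2_path) {
    rs <- default_read_structure(cfg, "map")
    frag_len <- cfg$oligo_len + nchar(sim_flank_up()) + cfg$barcode_len
    min_ov <- 10L
    if (2L * cfg$read_len - frag_len < min_ov)
        stop("read_len too short for fragment length ", frag_len,
             ": need read_len >= ", ceiling((frag_len + min_ov) / 2))
    n <- cfg$reads_step1
    with_seed_(cfg$seed + 1L, {
        bidx <- sample.int(length(truth$abundance), n, replace = TRUE,
                           prob = truth$abundance)
        bc <- truth$barcode_map$barcode[bidx]
        ol <- truth$oligos[truth$barcode_map$oligo_id[bidx]]
        frags <- paste0(ol, sim_flank_up(), bc)
        r1 <- substr(frags, 1L, cfg$read_len)
        r2 <- revcomp_cpp(substr(frags, frag_len - cfg$read_len + 1L,
                                 frag_len))
        r1 <- add_errors_(r1, cfg$error_rate)
        r2 <- add_errors_(r2, cfg$error_rate)
        qual <- phred_string_(cfg$error_rate, cfg$read_len)
        ids <- paste0("frag", seq_len(n))
        write_fastq_(ids, r1, rep(qual, n), r1_path)
        write_fastq_(ids, r2, rep(qual, n), r2_path)
    })
    invisible(c(r1_path, r2_path))
}

#' Emit barcode-counting reads (simulated steps 2 and 3)
#'
#' DNA reads sample barcodes proportionally to their true abundance;
#' RNA reads proportionally to abundance times the true activity of the
#' barcode's oligo (renormalized). Each replicate is an independent
#' multinomial draw. Reads are `linker + barcode` with substitution
#' errors. Deterministic given (`cfg$seed`, `role`, `replicate`).
#'
#' @inheritParams emit_step1_reads
#' @param role `"dna"` or `"rna"`.
#' @param replicate Replicate index (1-based).
#' @param path Output FASTQ path (`.gz` suffix gzips).
#' @return Invisibly, `path`.
#' @export
emit_count_reads <- function(truth, cfg, role = c("dna", "rna"),
                             replicate = 1L, path) {
    role <- match.arg(role)
    prob <- truth$abundance
    if (role == "rna") {
        prob <- prob * truth$activity[truth$barcode_map$oligo_id]
        prob <- prob / sum(prob)
    }
    n <- if (role == "dna") cfg$reads_dna else cfg$reads_rna
    offset <- if (role == "dna") 100L else 200L
    with_seed_(cfg$seed + offset + as.integer(replicate), {
        bidx <- sample.int(length(prob), n, replace = TRUE, prob = prob)
        reads <- paste0(sim_flank_up(), truth$barcode_map$barcode[bidx])
        reads <- add_errors_(reads, cfg$error_rate)
        len <- nchar(sim_flank_up()) + cfg$barcode_len
        qual <- phred_string_(cfg$error_rate, len)
        write_fastq_(paste0(role, "_r", replicate, "_", seq_len(n)),
                     reads, rep(qual, n), path)
    })
    invisible(path)
}

#' Write the simulated oligo library as FASTA
#' @param truth An `mpra_truth`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_truth_library <- function(truth, path) {
    set <- Biostrings::DNAStringSet(truth$oligos)
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Write the ground-truth tables as TSV
#' @param truth An `mpra_truth`.
#' @param outdir Output directory.
#' @return Invisibly, paths of the three truth tables.
#' @export
write_truth_tables <- function(truth, outdir = ".") {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(outdir, "truth_oligos.tsv")
    write_table(data.frame(oligo_id = names(truth$oligos),
                           sequence = unname(truth$oligos),
                           true_activity = unname(truth$activity),
                           stringsAsFactors = FALSE), p1)
    p2 <- file.path(outdir, "truth_barcode_map.tsv")
    write_table(data.frame(truth$barcode_map,
                           abundance = unname(truth$abundance),
                           stringsAsFactors = FALSE), p2)
    invisible(c(p1, p2))
}
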