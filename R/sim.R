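STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

#' Simulation configuration for a synthetic heterograft experiment
#'
#' Bundles every tunable of the synthetic data generator. Defaults emulate
#' the study design the package targets: two transcriptomes at ~4% nucleotide
#' divergence, 85-bp stranded paired-end reads, three biological replicates,
#' and four growth conditions (full nutrition and N, P, Fe starvation) under
#' which a minority of scion transcripts is graft-transmitted into the
#' rootstock at low abundance.
#'
#' @param n_transcripts number of transcripts per reference set.
#' @param length_range transcript length bounds in bp.
#' @param divergence expected per-site substitution divergence between the
#'   scion and rootstock lineages (default 0.04, i.e. 96% identity).
#' @param indel_rate expected per-site indel divergence between lineages; in
#'   coding mode indels are whole codons so reading frames are preserved.
#' @param read_length read length in bp (default 85).
#' @param error_rate per-base sequencing substitution error probability.
#' @param depth mean read-pair count per expressed rootstock transcript.
#' @param mobile_abundance_factor ratio of mobile scion transcript depth to
#'   rootstock transcript depth (mobile mRNAs arrive at low abundance).
#' @param n_replicates biological replicates per condition (default 3).
#' @param conditions ordered condition labels.
#' @param insert_range fragment insert size bounds in bp.
#' @param adapter 3' sequencing adapter that appears on short-insert reads.
#' @param adapter_fraction fraction of pairs with adapter read-through
#'   (insert shorter than the read length).
#' @param rrna_fraction expected ribosomal-RNA contaminant pairs as a
#'   fraction of the sample's mRNA pairs.
#' @param lowq_fraction fraction of mates carrying a low-quality 3' tail.
#' @param coding if `TRUE`, transcripts are stop-free open reading frames
#'   (ATG ... stop) and divergence avoids creating premature stop codons,
#'   mimicking purifying selection; needed for meaningful proteome tests.
#' @param master_seed integer master seed; every per-sample seed is derived
#'   deterministically from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 300,
                       length_range = c(500, 2000),
                       divergence = 0.04,
                       indel_rate = 0.002,
                       read_length = 85,
                       error_rate = 0.005,
                       depth = 30,
                       mobile_abundance_factor = 0.7,
                       n_replicates = 3,
                       conditions = c("full", "lowN", "lowP", "lowFe"),
                       insert_range = c(150, 400),
                       adapter = "AGATCGGAAGAGC",
                       adapter_fraction = 0.02,
                       rrna_fraction = 0.02,
                       lowq_fraction = 0.05,
                       coding = TRUE,
                       master_seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              length_range = as.integer(length_range),
              divergence = divergence, indel_rate = indel_rate,
              read_length = as.integer(read_length),
              error_rate = error_rate, depth = depth,
              mobile_abundance_factor = mobile_abundance_factor,
              n_replicates = as.integer(n_replicates),
              conditions = conditions,
              insert_range = as.integer(insert_range),
              adapter = adapter, adapter_fraction = adapter_fraction,
              rrna_fraction = rrna_fraction, lowq_fraction = lowq_fraction,
              coding = isTRUE(coding),
              master_seed = as.integer(master_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_transcripts < 0) stop("n_transcripts must be >= 0")
  if (length(cfg$length_range) != 2 || cfg$length_range[1] > cfg$length_range[2] ||
      cfg$length_range[1] < 3)
    stop("length_range must be increasing bounds >= 3")
  if (cfg$divergence < 0 || cfg$divergence > 0.5)
    stop("divergence must lie in [0, 0.5]")
  if (cfg$read_length < 40) stop("read_length must be >= 40")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  rates <- c(cfg$indel_rate, cfg$error_rate, cfg$adapter_fraction,
             cfg$rrna_fraction, cfg$lowq_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$mobile_abundance_factor < 0) stop("mobile_abundance_factor must be >= 0")
  if (cfg$depth < 0) stop("depth must be >= 0")
  invisible(cfg)
}

random_sense_codons <- function(n) {
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste0, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  sample(codons, n, replace = TRUE)
}

#' Generate an ancestral transcript set
#'
#' Draws `n_transcripts` sequences with lengths uniform over `length_range`.
#' In coding mode each transcript is an open reading frame: an ATG start,
#' stop-free sense codons, and a terminal stop codon (length is the nearest
#' multiple of three inside the range); otherwise bases are i.i.d. uniform.
#'
#' @param config a [sim_config()].
#' @return a [transcript_set()] with species id `"ancestor"`.
#' @export
generate_ancestor <- function(config) {
  validate_sim_config(config)
  n <- config$n_transcripts
  if (n == 0) return(transcript_set(character(0), "ancestor"))
  with_seed(derive_seed(config$master_seed, "ancestor"), {
    seqs <- character(n)
    if (config$coding) {
      lo <- ceiling(config$length_range[1] / 3)
      hi <- floor(config$length_range[2] / 3)
      ncod <- sample(seq(lo, hi), n, replace = TRUE)
      for (i in seq_len(n)) {
        body <- random_sense_codons(ncod[i] - 2L)
        seqs[i] <- paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
      }
    } else {
      lens <- sample(seq(config$length_range[1], config$length_range[2]),
                     n, replace = TRUE)
      for (i in seq_len(n))
        seqs[i] <- paste(sample(BASES, lens[i], replace = TRUE), collapse = "")
    }
    names(seqs) <- sprintf("t%04d", seq_len(n))
    transcript_set(seqs, "ancestor")
  })
}

# Substitute bases at `rate` per site; in coding mode a substitution that
# would create a premature in-frame stop codon is redrawn among the other
# alternatives (at least one non-stop alternative always exists).
mutate_substitutions <- function(seq, rate, coding) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sites <- which(runif(n) < rate)
  if (length(sites) == 0) return(seq)
  last_codon <- floor((n - 1) / 3)  # 0-based codon index of the final codon
  for (s in sites) {
    alts <- sample(setdiff(BASES, chars[s]))
    for (a in alts) {
      if (coding) {
        ci <- (s - 1) %/% 3
        if (ci < last_codon) {
          cs <- ci * 3 + 1
          cod <- chars[cs:(cs + 2)]
          cod[s - cs + 1] <- a
          if (paste(cod, collapse = "") %in% STOP_CODONS) next
        }
      }
      chars[s] <- a
      break
    }
  }
  paste(chars, collapse = "")
}

# Whole-codon (coding) or single-base indels at an expected per-site rate.
mutate_indels <- function(seq, per_site_rate, coding) {
  if (per_site_rate <= 0) return(seq)
  if (coding) {
    ncod <- nchar(seq) %/% 3
    if (ncod <= 2) return(seq)
    idx <- 2:(ncod - 1)                    # protect start and stop codons
    hit <- idx[runif(length(idx)) < per_site_rate * 3]
    if (length(hit) == 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (ci in rev(hit)) {
      pos <- (ci - 1) * 3 + 1
      if (runif(1) < 0.5) {
        chars <- chars[-(pos:(pos + 2))]
      } else {
        ins <- strsplit(random_sense_codons(1), "", fixed = TRUE)[[1]]
        chars <- append(chars, ins, after = pos - 1)
      }
    }
    paste(chars, collapse = "")
  } else {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < per_site_rate)
    if (length(hit) == 0) return(seq)
    for (s in rev(hit)) {
      if (runif(1) < 0.5) chars <- chars[-s]
      else chars <- append(chars, sample(BASES, 1), after = s - 1)
    }
    paste(chars, collapse = "")
  }
}

#' Diverge an ancestor into scion and rootstock transcript sets
#'
#' Each lineage independently receives per-site substitutions and indels so
#' that the expected pairwise substitution divergence between the two
#' lineages equals `config$divergence`. The per-lineage substitution rate is
#' solved from the pairwise target (two independent mutations can coincide
#' or collide at a site), so the realized between-lineage divergence is
#' unbiased. Transcript ids are retained in both outputs: the id-level
#' correspondence is the ground-truth orthology.
#'
#' @param ancestor a [transcript_set()].
#' @param config a [sim_config()].
#' @return list with elements `scion` and `rootstock`.
#' @export
diverge <- function(ancestor, config) {
  stopifnot(inherits(ancestor, "transcript_set"))
  validate_sim_config(config)
  if (length(ancestor) == 0) stop("ancestor set is empty")
  d <- config$divergence
  # pairwise p = 2r - (4/3) r^2  =>  per-lineage rate r
  r <- if (d > 0) (2 - sqrt(4 - (16 / 3) * d)) * 3 / 8 else 0
  half_indel <- config$indel_rate / 2
  lineage <- function(tag) {
    with_seed(derive_seed(config$master_seed, "diverge", tag), {
      seqs <- vapply(ancestor$sequences, function(s) {
        s <- mutate_substitutions(s, r, config$coding)
        mutate_indels(s, half_indel, config$coding)
      }, character(1))
      transcript_set(seqs, tag)
    })
  }
  list(scion = lineage("scion"), rootstock = lineage("rootstock"))
}

#' Assign the ground-truth mobile transcript sets
#'
#' Samples disjoint Venn regions over the growth conditions from the scion
#' transcript ids: a region signature such as `"full+lowN"` receives
#' transcripts mobile under exactly those conditions.
#'
#' @param scion scion [transcript_set()].
#' @param region_sizes named integer vector; names are `+`-joined subsets of
#'   `conditions`, values the number of transcripts in each exclusive region.
#' @param seed integer seed for the sampling.
#' @param conditions ordered condition labels.
#' @return object of class `sim_truth`: list with `mobile_by_condition`
#'   (per condition, the ids mobile under it), `regions` (exclusive Venn
#'   regions) and `conditions`.
#' @export
assign_truth <- function(scion, region_sizes, seed = 1L,
                         conditions = c("full", "lowN", "lowP", "lowFe")) {
  stopifnot(inherits(scion, "transcript_set"))
  sizes <- as.integer(region_sizes)
  names(sizes) <- names(region_sizes)
  if (length(sizes) > 0 && (is.null(names(sizes)) || any(names(sizes) == "")))
    stop("region_sizes must be named by '+'-joined condition signatures")
  for (sig in names(sizes)) {
    conds <- strsplit(sig, "+", fixed = TRUE)[[1]]
    if (!all(conds %in% conditions))
      stop("unknown condition in region signature: ", sig)
  }
  if (sum(sizes) > length(scion))
    stop("region sizes (", sum(sizes), ") exceed transcript count (",
         length(scion), ")")
  with_seed(seed, {
    pool <- sample(transcript_ids(scion))
    regions <- list()
    offset <- 0L
    for (sig in names(sizes)) {
      k <- sizes[[sig]]
      regions[[sig]] <- if (k > 0) sort(pool[(offset + 1):(offset + k)]) else character(0)
      offset <- offset + k
    }
    mobile <- lapply(conditions, function(cond) {
      ids <- unlist(regions[vapply(names(regions), function(sig)
        cond %in% strsplit(sig, "+", fixed = TRUE)[[1]], logical(1))],
        use.names = FALSE)
      sort(unique(ids))
    })
    names(mobile) <- conditions
    structure(list(mobile_by_condition = mobile, regions = regions,
                   conditions = conditions),
              class = "sim_truth")
  })
}

#' Default ground-truth Venn structure
#'
#' A condition-overlap structure qualitatively mirroring a heterograft
#' experiment in which a core of transcripts is mobile under every
#' condition, each mineral starvation induces mobility of its own specific
#' minority, and a few transcripts are shared between full nutrition and one
#' stress. Scaled for a 300-transcript desk-scale reference.
#'
#' @return named integer vector usable as `region_sizes` in [assign_truth()].
#' @export
default_truth_regions <- function() {
  c("full+lowN+lowP+lowFe" = 28L, "full" = 4L,
    "lowN" = 15L, "lowP" = 11L, "lowFe" = 14L,
    "full+lowN" = 3L, "full+lowP" = 2L, "full+lowFe" = 3L)
}

#' Generate a ribosomal RNA contaminant reference
#'
#' @param config a [sim_config()].
#' @param n number of rRNA sequences.
#' @param length_range rRNA length bounds in bp.
#' @return a [transcript_set()] with species id `"rrna"`.
#' @export
generate_rrna <- function(config, n = 3, length_range = c(1500, 1900)) {
  validate_sim_config(config)
  with_seed(derive_seed(config$master_seed, "rrna"), {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
    names(seqs) <- sprintf("rRNA_%d", seq_len(n))
    transcript_set(seqs, "rrna")
  })
}

# inject substitution errors at `rate` per base
apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

make_qualities <- function(n, read_length, lowq_fraction) {
  qual <- rep(strrep("F", read_length), n)           # Phred 37 baseline
  low <- which(runif(n) < lowq_fraction)
  if (length(low) > 0) {
    tails <- sample(6:15, length(low), replace = TRUE)
    qual[low] <- paste0(strrep("F", read_length - tails), strrep(")", tails))
  }
  qual
}

#' Simulate one sequenced sample of a heterograft experiment
#'
#' Grafted samples contain read pairs from every rootstock transcript at
#' mean depth `config$depth` plus pairs from the scion transcripts mobile
#' under `condition` at `depth * mobile_abundance_factor`; non-grafted
#' control samples contain rootstock reads only. Mate 1 is sequenced from
#' the sense strand, mate 2 is the reverse complement of the fragment's 3'
#' end (dUTP-like stranded protocol). Short-insert pairs read through into
#' the 3' adapter; rRNA contaminant pairs are injected at
#' `config$rrna_fraction`. Every pair id records its source transcript,
#' origin class, condition and replicate, so downstream calls can be scored
#' against the truth.
#'
#' @param rootstock,scion [transcript_set()] references.
#' @param truth a `sim_truth` from [assign_truth()].
#' @param condition condition label (must be in `truth$conditions`).
#' @param replicate replicate index.
#' @param config a [sim_config()].
#' @param grafted if `FALSE`, simulate a non-grafted control (no scion reads).
#' @param rrna optional rRNA [transcript_set()] for contaminant pairs.
#' @return a `read_pairs` data frame (pair_id, seq1, qual1, seq2, qual2)
#'   with sample metadata attributes.
#' @export
simulate_sample <- function(rootstock, scion, truth, condition, replicate,
                            config, grafted = TRUE, rrna = NULL) {
  stopifnot(inherits(rootstock, "transcript_set"),
            inherits(scion, "transcript_set"),
            inherits(truth, "sim_truth"))
  validate_sim_config(config)
  if (!condition %in% truth$conditions)
    stop("unknown condition: ", condition)
  L <- config$read_length
  seed <- derive_seed(config$master_seed, "sample", condition, replicate,
                      if (grafted) "grafted" else "control")
  with_seed(seed, {
    sources <- data.frame(id = transcript_ids(rootstock),
                          seq = unname(rootstock$sequences),
                          origin = "rootstock",
                          depth = config$depth,
                          stringsAsFactors = FALSE)
    if (grafted) {
      mob <- truth$mobile_by_condition[[condition]]
      if (length(mob) > 0) {
        sources <- rbind(sources, data.frame(
          id = mob, seq = unname(scion$sequences[mob]), origin = "scion",
          depth = config$depth * config$mobile_abundance_factor,
          stringsAsFactors = FALSE))
      }
    }
    short <- nchar(sources$seq) < L
    if (any(short)) {
      warning("excluding ", sum(short), " transcript(s) shorter than the read length")
      sources <- sources[!short, , drop = FALSE]
    }
    npairs <- rpois(nrow(sources), sources$depth)
    main <- emit_pairs(sources, npairs, config)
    total_main <- sum(npairs)
    if (!is.null(rrna) && config$rrna_fraction > 0 && total_main > 0) {
      nr <- rpois(1, config$rrna_fraction * total_main)
      if (nr > 0) {
        rsrc <- data.frame(id = transcript_ids(rrna),
                           seq = unname(rrna$sequences), origin = "rrna",
                           depth = NA, stringsAsFactors = FALSE)
        alloc <- tabulate(sample.int(nrow(rsrc), nr, replace = TRUE),
                          nbins = nrow(rsrc))
        main <- rbind(main, emit_pairs(rsrc, alloc, config))
      }
    }
    if (nrow(main) == 0) {
      return(read_pairs(data.frame(pair_id = character(0), seq1 = character(0),
                                   qual1 = character(0), seq2 = character(0),
                                   qual2 = character(0)),
                        condition, replicate, grafted))
    }
    main$seq1 <- apply_errors(main$seq1, config$error_rate)
    main$seq2 <- apply_errors(main$seq2, config$error_rate)
    qual1 <- make_qualities(nrow(main), L, config$lowq_fraction)
    qual2 <- make_qualities(nrow(main), L, config$lowq_fraction)
    tag <- if (grafted) condition else "control"
    ids <- sprintf("p%06d|src:%s|org:%s|cond:%s|rep:%d",
                   seq_len(nrow(main)), main$src, main$org, tag, replicate)
    read_pairs(data.frame(pair_id = ids, seq1 = main$seq1, qual1 = qual1,
                          seq2 = main$seq2, qual2 = qual2,
                          stringsAsFactors = FALSE),
               condition, replicate, grafted)
  })
}

# fragment sampling shared by mRNA and rRNA sources
emit_pairs <- function(sources, npairs, config) {
  L <- config$read_length
  out <- vector("list", nrow(sources))
  for (i in seq_len(nrow(sources))) {
    n <- npairs[i]
    if (n == 0) next
    tlen <- nchar(sources$seq[i])
    adapt <- runif(n) < config$adapter_fraction
    lo <- min(config$insert_range[1], tlen)
    hi <- min(config$insert_range[2], tlen)
    lo <- max(lo, L)  # normal fragments fully cover a read
    insert <- lo + floor(runif(n) * (hi - lo + 1))
    if (any(adapt))
      insert[adapt] <- 20 + floor(runif(sum(adapt)) * (L - 20))
    start <- floor(runif(n) * (tlen - insert + 1))
    frag <- substr(rep(sources$seq[i], n), start + 1, start + insert)
    pad <- function(x) {
      need <- pmax(L - nchar(x), 0)
      fill <- substr(rep(paste0(config$adapter, strrep("G", L)), length(x)),
                     1, need)
      paste0(x, fill)
    }
    seq1 <- pad(substr(frag, 1, pmin(L, insert)))
    seq2 <- pad(revcomp(substr(frag, pmax(1, insert - L + 1), insert)))
    out[[i]] <- data.frame(src = sources$id[i], org = sources$origin[i],
                           seq1 = seq1, seq2 = seq2, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(src = character(0), org = character(0),
                      seq1 = character(0), seq2 = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read-pair container
#'
#' @param df data frame with columns pair_id, seq1, qual1, seq2, qual2.
#' @param condition,replicate,grafted sample metadata.
#' @return the data frame with class `read_pairs` and metadata attributes.
#' @export
read_pairs <- function(df, condition = NA, replicate = NA, grafted = NA) {
  need <- c("pair_id", "seq1", "qual1", "seq2", "qual2")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (nrow(df) > 0) {
    if (any(nchar(df$seq1) != nchar(df$qual1)) ||
        any(nchar(df$seq2) != nchar(df$qual2)))
      stop("sequence and quality lengths differ")
    if (anyDuplicated(df$pair_id)) stop("duplicate pair ids")
  }
  structure(df, class = c("read_pairs", "data.frame"),
            condition = condition, replicate = replicate, grafted = grafted)
}

#' Parse ground-truth fields from simulated pair ids
#'
#' @param pair_ids character vector of simulated pair ids.
#' @return data frame with columns `src` (source transcript), `org`
#'   (rootstock/scion/rrna), `cond`, `rep`.
#' @export
parse_read_names <- function(pair_ids) {
  parts <- strsplit(pair_ids, "|", fixed = TRUE)
  grab <- function(p, key) {
    v <- p[startsWith(p, paste0(key, ":"))]
    if (length(v) == 0) NA_character_ else sub(paste0("^", key, ":"), "", v[1])
  }
  data.frame(src = vapply(parts, grab, character(1), "src"),
             org = vapply(parts, grab, character(1), "org"),
             cond = vapply(parts, grab, character(1), "cond"),
             rep = as.integer(vapply(parts, grab, character(1), "rep")),
             stringsAsFactors = FALSE)
}

#' Translate transcript sets into proteomes
#'
#' Naive single-frame translation (standard codon table): each sequence is
#' truncated to a codon multiple, translated, and cut at the first stop.
#'
#' @param scion,rootstock [transcript_set()] objects (sequences >= 3 bp).
#' @return list with named character vectors `scion` and `rootstock`.
#' @export
generate_proteomes <- function(scion, rootstock) {
  list(scion = translate_naive(scion$sequences),
       rootstock = translate_naive(rootstock$sequences))
}

#' Naive single-frame translation
#' @param seqs named character vector of nucleotide sequences.
#' @return named character vector of amino-acid sequences (stop-truncated).
#' @export
translate_naive <- function(seqs) {
  stopifnot(all(nchar(seqs) >= 3))
  trimmed <- substr(seqs, 1, (nchar(seqs) %/% 3) * 3)
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed)))
  aa <- sub("\\*.*$", "", aa)
  names(aa) <- names(seqs)
  aa
}

#' Simulate a complete heterograft experiment
#'
#' Convenience wrapper: ancestor, diverged references, rRNA reference,
#' ground-truth mobile sets, grafted samples for every condition and
#' replicate, non-grafted controls, and translated proteomes.
#'
#' @param config a [sim_config()].
#' @param region_sizes Venn region sizes for [assign_truth()].
#' @param n_control_replicates number of non-grafted control samples.
#' @return list with `config`, `rootstock`, `scion`, `rrna`, `truth`,
#'   `samples` (named `condition.replicate` list of `read_pairs`),
#'   `controls`, and `proteomes`.
#' @export
simulate_experiment <- function(config = sim_config(),
                                region_sizes = default_truth_regions(),
                                n_control_replicates = config$n_replicates) {
  validate_sim_config(config)
  anc <- generate_ancestor(config)
  refs <- diverge(anc, config)
  rrna <- generate_rrna(config)
  truth <- assign_truth(refs$scion, region_sizes,
                        seed = derive_seed(config$master_seed, "truth"),
                        conditions = config$conditions)
  samples <- list()
  for (cond in config$conditions) {
    for (r in seq_len(config$n_replicates)) {
      samples[[paste(cond, r, sep = ".")]] <-
        simulate_sample(refs$rootstock, refs$scion, truth, cond, r, config,
                        grafted = TRUE, rrna = rrna)
    }
  }
  controls <- lapply(seq_len(n_control_replicates), function(r)
    simulate_sample(refs$rootstock, refs$scion, truth,
                    config$conditions[1], r, config, grafted = FALSE,
                    rrna = rrna))
  list(config = config, rootstock = refs$rootstock, scion = refs$scion,
       rrna = rrna, truth = truth, samples = samples, controls = controls,
       proteomes = generate_proteomes(refs$scion, refs$rootstock))
}
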