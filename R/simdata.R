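# run expr under a local seeded RNG without touching global random state
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed < 2^31)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic truth transcriptome
#'
#' Uniform-random A/C/G/T transcripts with lengths uniform on
#' `length_range`, ids `tx000001`, `tx000002`, ... Output is a pure function
#' of the arguments and seed.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_range Integer pair `(min, max)` bp, `100 <= min <= max`.
#' @param seed Integer seed.
#' @return An [assembly] labelled `"truth"`.
#' @export
generate_truth <- function(n_transcripts, length_range = c(200L, 2000L),
                           seed = 1L) {
  stopifnot(n_transcripts >= 1, length(length_range) == 2L)
  if (!(length_range[1L] >= 100 && length_range[1L] <= length_range[2L]))
    stop("invalid length range: need 100 <= min <= max")
  with_seed(seed, {
    span <- length_range[2L] - length_range[1L] + 1L
    lens <- length_range[1L] +
      sample.int(span, n_transcripts, replace = TRUE) - 1L
    seqs <- vapply(lens, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), character(1))
    assembly(sprintf("tx%06d", seq_len(n_transcripts)), seqs,
             label = "truth")
  })
}

#' Simulated-assembler behavior profile
#'
#' Describes how a simulated assembler degrades the truth: what fraction of
#' transcripts it reconstructs (`sensitivity`), what fraction of those it
#' splits in two (`fragmentation_rate`) and what fraction it emits twice
#' (`redundancy_rate`).
#'
#' @param sensitivity,fragmentation_rate,redundancy_rate Proportions in
#'   \[0, 1\].
#' @param seed Integer seed driving every lottery in
#'   [simulate_assembly()].
#' @return A list of class `sim_profile`.
#' @export
sim_profile <- function(sensitivity = 1, fragmentation_rate = 0,
                        redundancy_rate = 0, seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            fragmentation_rate >= 0, fragmentation_rate <= 1,
            redundancy_rate >= 0, redundancy_rate <= 1)
  structure(list(sensitivity = sensitivity,
                 fragmentation_rate = fragmentation_rate,
                 redundancy_rate = redundancy_rate,
                 seed = as.integer(seed)),
            class = "sim_profile")
}

#' Simulate a degraded candidate assembly
#'
#' Deterministically subsamples the truth (transcripts sorted by id, seeded
#' shuffle, prefix of size `floor(sensitivity * n)`), splits a
#' `fragmentation_rate` fraction of the kept transcripts at a random
#' interior point at least 100 bp from each end (when the transcript is long
#' enough; otherwise at the midpoint), duplicates a `redundancy_rate`
#' fraction verbatim, and shuffles the output order.
#'
#' @param truth Nonempty truth [assembly].
#' @param profile A [sim_profile].
#' @param label Label of the simulated assembly.
#' @return An [assembly].
#' @export
simulate_assembly <- function(truth, profile, label = "sim") {
  stopifnot(inherits(truth, "assembly"), inherits(profile, "sim_profile"))
  if (length(truth$ids) == 0L) stop("truth assembly is empty")
  with_seed(profile$seed, {
    ord <- order(truth$ids)
    ids <- truth$ids[ord]
    seqs <- truth$sequences[ord]
    n <- length(ids)
    shuffle <- sample.int(n)
    keep <- shuffle[seq_len(floor(profile$sensitivity * n))]
    ids <- ids[keep]
    seqs <- seqs[keep]
    k <- length(ids)
    out_ids <- character(0)
    out_seqs <- character(0)
    if (k > 0L) {
      n_frag <- floor(profile$fragmentation_rate * k)
      frag <- seq_len(k) %in% sample.int(k, n_frag)
      for (i in seq_len(k)) {
        len <- nchar(seqs[i])
        if (frag[i]) {
          p <- if (len >= 200L) 99L + sample.int(len - 199L, 1L)
               else max(1L, len %/% 2L)
          out_ids <- c(out_ids, paste0(ids[i], "_a"), paste0(ids[i], "_b"))
          out_seqs <- c(out_seqs, substr(seqs[i], 1L, p),
                        substr(seqs[i], p + 1L, len))
        } else {
          out_ids <- c(out_ids, ids[i])
          out_seqs <- c(out_seqs, seqs[i])
        }
      }
      n_dup <- floor(profile$redundancy_rate * k)
      if (n_dup > 0L) {
        dup <- sample.int(length(out_ids), n_dup)
        out_ids <- c(out_ids, paste0(out_ids[dup], "_dup"))
        out_seqs <- c(out_seqs, out_seqs[dup])
      }
      ord2 <- sample.int(length(out_ids))
      out_ids <- out_ids[ord2]
      out_seqs <- out_seqs[ord2]
    }
    assembly(out_ids, out_seqs, label = label)
  })
}

#' Simulate error-free reads from a truth transcriptome
#'
#' Substrings of length `read_len` at uniform random positions across the
#' transcriptome (transcripts weighted by the number of start positions they
#' offer), on a random strand, written as FASTQ with constant quality `I`.
#'
#' @param truth Nonempty [assembly]; `read_len` must not exceed the shortest
#'   transcript.
#' @param n_reads Number of reads.
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @param path Output FASTQ path (default a file under `tempdir()`).
#' @return The FASTQ path, invisibly.
#' @export
simulate_reads <- function(truth, n_reads, read_len, seed = 1L,
                           path = tempfile(fileext = ".fastq")) {
  stopifnot(inherits(truth, "assembly"), n_reads >= 1, read_len >= 1)
  if (read_len > min(truth$lengths))
    stop("read_len ", read_len, " exceeds the shortest transcript (",
         min(truth$lengths), " bp)")
  with_seed(seed, {
    weights <- truth$lengths - read_len + 1L
    tx <- sample.int(length(truth$ids), n_reads, replace = TRUE,
                     prob = weights)
    start <- vapply(tx, function(i)
      sample.int(truth$lengths[i] - read_len + 1L, 1L), integer(1))
    seqs <- substr(truth$sequences[tx], start, start + read_len - 1L)
    flip <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
    seqs[flip] <- revcomp(seqs[flip])
    qual <- strrep("I", read_len)
    lines <- as.vector(rbind(sprintf("@read%06d", seq_len(n_reads)),
                             seqs, "+", qual))
    writeLines(lines, path)
  })
  invisible(path)
}

#' Derive a marker set from a truth transcriptome
#'
#' One substring of `marker_len` from each of `n_markers` distinct
#' transcripts, chosen with a seeded lottery.
#'
#' @param truth Nonempty [assembly].
#' @param n_markers Number of markers (`<=` transcript count).
#' @param marker_len Marker length in bp (`>= 100`, `<=` shortest
#'   transcript).
#' @param seed Integer seed.
#' @return A [marker_set].
#' @export
derive_markers <- function(truth, n_markers, marker_len = 150L, seed = 1L) {
  stopifnot(inherits(truth, "assembly"))
  if (n_markers > length(truth$ids))
    stop("n_markers exceeds the transcript count")
  if (marker_len > min(truth$lengths))
    stop("marker_len exceeds the shortest transcript")
  if (marker_len < 100L) stop("marker_len must be at least 100")
  with_seed(seed, {
    tx <- sample.int(length(truth$ids), n_markers)
    start <- vapply(tx, function(i)
      sample.int(truth$lengths[i] - marker_len + 1L, 1L), integer(1))
    marker_set(sprintf("marker%04d", seq_len(n_markers)),
               substr(truth$sequences[tx], start, start + marker_len - 1L))
  })
}

#' Generate a complete synthetic test design on disk
#'
#' Writes, under `dir`: a truth FASTA and a markers FASTA per dataset, one
#' candidate-assembly FASTA per (assembler, dataset) cell, a reads FASTQ per
#' dataset, and `manifest.txt` (key=value lines) recording every seed and
#' parameter. Simulated assembler profiles are drawn deterministically from
#' `seed`: sensitivities spread over [0.6, 0.95], fragmentation over
#' [0, 0.3], redundancy over [0, 0.2]; the first assembler (`asm1`) is the
#' conventional baseline.
#'
#' @param dir Output directory.
#' @param n_assemblers Number of simulated assemblers (default 4).
#' @param n_datasets Number of datasets (default 2).
#' @param n_transcripts Transcripts per truth set (default 60).
#' @param length_range Truth transcript length range (default 250-1200 bp).
#' @param n_reads Reads per dataset (default 400).
#' @param read_len Read length (default 75).
#' @param n_markers Markers per dataset (default 20).
#' @param marker_len Marker length (default 150).
#' @param seed Master seed; all per-file seeds derive from it.
#' @return The manifest path, invisibly.
#' @export
make_fixture <- function(dir, n_assemblers = 4L, n_datasets = 2L,
                         n_transcripts = 60L, length_range = c(250L, 1200L),
                         n_reads = 400L, read_len = 75L, n_markers = 20L,
                         marker_len = 150L, seed = 1L) {
  stopifnot(n_assemblers >= 1, n_datasets >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed) %% 100000L
  asm_names <- paste0("asm", seq_len(n_assemblers))
  profiles <- with_seed(seed, lapply(seq_len(n_assemblers), function(i) {
    sim_profile(
      sensitivity = if (i == 1L) 0.8 else stats::runif(1, 0.6, 0.95),
      fragmentation_rate = stats::runif(1, 0, 0.3),
      redundancy_rate = stats::runif(1, 0, 0.2),
      seed = seed + 1000L * i)
  }))
  man <- c(sprintf("seed=%d", seed),
           sprintf("n_assemblers=%d", n_assemblers),
           sprintf("n_datasets=%d", n_datasets),
           sprintf("n_transcripts=%d", n_transcripts),
           sprintf("length_range=%d,%d", length_range[1L], length_range[2L]),
           sprintf("n_reads=%d", n_reads),
           sprintf("read_len=%d", read_len),
           sprintf("n_markers=%d", n_markers),
           sprintf("marker_len=%d", marker_len),
           sprintf("baseline=%s", asm_names[1L]),
           sprintf("assemblers=%s", paste(asm_names, collapse = ",")),
           sprintf("datasets=%s",
                   paste(paste0("ds", seq_len(n_datasets)), collapse = ",")))
  for (i in seq_len(n_assemblers))
    man <- c(man, sprintf(
      "profile.%s=sensitivity:%.4f,fragmentation:%.4f,redundancy:%.4f,seed:%d",
      asm_names[i], profiles[[i]]$sensitivity,
      profiles[[i]]$fragmentation_rate, profiles[[i]]$redundancy_rate,
      profiles[[i]]$seed))
  for (d in seq_len(n_datasets)) {
    ds <- paste0("ds", d)
    truth <- generate_truth(n_transcripts, length_range,
                            seed = seed + 17L * d)
    truth$label <- paste0("truth_", ds)
    write_fasta(truth, file.path(dir, paste0("truth_", ds, ".fasta")))
    mk <- derive_markers(truth, n_markers, marker_len,
                         seed = seed + 17L * d + 7L)
    write_fasta(assembly(mk$ids, mk$sequences, label = "markers"),
                file.path(dir, paste0("markers_", ds, ".fasta")))
    simulate_reads(truth, n_reads, read_len, seed = seed + 17L * d + 3L,
                   path = file.path(dir, paste0("reads_", ds, ".fastq")))
    for (i in seq_len(n_assemblers)) {
      pr <- profiles[[i]]
      pr$seed <- pr$seed + d  # dataset-specific lottery per assembler
      a <- simulate_assembly(truth, pr, label = asm_names[i])
      write_fasta(a, file.path(dir, sprintf("%s_%s.fasta",
                                            asm_names[i], ds)))
    }
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(man, manifest)
  invisible(manifest)
}

#' Read a fixture manifest
#'
#' @param dir Fixture directory written by [make_fixture()].
#' @return Named list of manifest values (character).
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.txt")
  if (!file.exists(path)) stop("no manifest.txt under ", dir)
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, character(1), 1L))
}

#' Load a fixture directory into memory
#'
#' @param dir Fixture directory written by [make_fixture()].
#' @return List with `assemblies` (nested dataset -> assembler ->
#'   [assembly]), `markers` (per-dataset [marker_set] list), `reads`
#'   (per-dataset FASTQ paths), `baseline`, `manifest`.
#' @export
load_fixture <- function(dir) {
  man <- read_manifest(dir)
  datasets <- strsplit(man$datasets, ",", fixed = TRUE)[[1L]]
  asm <- strsplit(man$assemblers, ",", fixed = TRUE)[[1L]]
  assemblies <- lapply(datasets, function(ds) {
    al <- lapply(asm, function(a) {
      x <- read_fasta(file.path(dir, sprintf("%s_%s.fasta", a, ds)))
      x$label <- a
      x
    })
    stats::setNames(al, asm)
  })
  names(assemblies) <- datasets
  markers <- lapply(datasets, function(ds) {
    m <- read_fasta(file.path(dir, paste0("markers_", ds, ".fasta")))
    marker_set(m$ids, m$sequences)
  })
  names(markers) <- datasets
  reads <- stats::setNames(
    file.path(dir, paste0("reads_", datasets, ".fastq")), datasets)
  list(assemblies = assemblies, markers = markers, reads = reads,
       baseline = man$baseline, manifest = man)
}
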