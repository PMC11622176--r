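#' Bundled action-count table for two subjects
#'
#' Published per-scene counts of actions chosen for bad objects by two
#' well-trained macaques (subjects C and S), used to calibrate the behavioral
#' ground truth and as a worked example for [proportion_table()] and
#' [fisher_stable_vs_flexible()].
#'
#' @param monkey `"C"` or `"S"`.
#' @return an [action_count_table()] for the requested subject.
#' @export
load_action_counts <- function(monkey = c("C", "S")) {
  monkey <- match.arg(monkey)
  path <- system.file("extdata", "bad_object_action_counts.csv",
                      package = "proactstriat", mustWork = TRUE)
  all <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- all[all$monkey == monkey, c("scene", "total", "accept", "return",
                                     "stay", "other", "fixbreak")]
  rownames(out) <- NULL
  structure(out, class = c("action_count_table", "data.frame"))
}

#' Write session tables to disk
#'
#' Writes `trials.csv`, per-trial eye traces under `eye/`, per-neuron spike
#' times under `spikes/`, and `ground_truth.json` (neuron parameters).
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if needed).
#' @param write_eye also write the (many) per-presentation eye-trace CSVs.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, write_eye = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  spdir <- file.path(dir, "spikes")
  dir.create(spdir, showWarnings = FALSE)
  for (id in names(session$spikes))
    utils::write.csv(data.frame(t_ms = session$spikes[[id]]),
                     file.path(spdir, paste0(id, ".csv")), row.names = FALSE)
  if (write_eye) {
    eyedir <- file.path(dir, "eye")
    dir.create(eyedir, showWarnings = FALSE)
    for (pid in names(session$eye))
      utils::write.csv(session$eye[[pid]],
                       file.path(eyedir, paste0(pid, ".csv")), row.names = FALSE)
  }
  gt <- lapply(session$ground_truth$neurons, function(nt) unclass(nt))
  write_json_file(gt, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
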