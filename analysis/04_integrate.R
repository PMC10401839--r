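#!/usr/bin/env Rscript
# Stage 4 — mixed-methods joint display.
#
# In the study design, caseworkers are shown each cluster's profile and
# asked whether they can recall recipients matching it; the analyst records
# one boolean per (cluster, interviewee) and the verdict per cluster is
# concordance (all yes), partial concordance (mixed) or discordance (all
# no). Interviews cannot be simulated, so this stage uses a SYNTHETIC
# response set with four interviewees whose per-cluster verdict pattern
# mirrors the published one (three concordant and two partially concordant
# female clusters; for males, three partially concordant and two discordant
# clusters), to exercise the classifier and the display end to end.

suppressPackageStartupMessages(library(segmint))

verdict_pattern <- list(
  male = c("partial", "partial", "partial", "discordance", "discordance"),
  female = c("concordance", "concordance", "partial", "concordance",
             "partial")
)
responses_for <- function(pattern) {
  do.call(rbind, lapply(seq_along(pattern), function(k) {
    yes <- switch(pattern[k],
                  concordance = c(TRUE, TRUE, TRUE, TRUE),
                  partial = c(TRUE, FALSE, TRUE, FALSE),
                  discordance = c(FALSE, FALSE, FALSE, FALSE))
    data.frame(cluster_id = k, interviewee_id = paste0("cw", 1:4),
               could_recall = yes)
  }))
}

displays <- list()
for (sex in c("male", "female")) {
  prof <- local({
    raw <- jsonlite::read_json(sprintf("results/profiles_%s.json", sex),
                               simplifyVector = TRUE)
    structure(lapply(seq_len(nrow(raw)), function(i) {
      lv <- raw$levels[[i]]
      if (is.null(lv) || length(lv) == 0L) {
        lv <- data.frame(variable = character(), level = character(),
                         affiliation = numeric())
      }
      list(cluster = raw$cluster[i], n_members = raw$n_members[i],
           levels = lv)
    }), class = "cluster_profiles")
  })
  responses <- responses_for(verdict_pattern[[sex]])
  write.csv(responses, sprintf("results/responses_synthetic_%s.csv", sex),
            row.names = FALSE)
  displays[[sex]] <- joint_display(prof, responses, sex = sex)
}
jd <- do.call(rbind, displays)
write.csv(jd, "results/joint_display.csv", row.names = FALSE)

cat("joint display (synthetic caseworker responses):\n")
print(jd[, c("sex", "cluster_id", "n_yes", "n_respondents", "verdict")],
      row.names = FALSE)
cat(sprintf("\nverdicts partition the clusters: %d rows for %d clusters\n",
            nrow(jd), sum(vapply(displays, nrow, integer(1)))))
cat("wrote results/joint_display.csv and results/responses_synthetic_{male,female}.csv\n")
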