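#!/usr/bin/env Rscript
# Score every simulated render with the trained model: anomaly score
# AS = (1 - lambda) R(X) + lambda D(X), standardized against the normal
# training images, then summarized by label.
suppressPackageStartupMessages(library(anoscore))

model <- load_gan_model("results/model")
meta <- read.csv("results/images/labels.csv")
images <- lapply(file.path("results/images", meta$file), read_image_png)

normals <- images[meta$label == "normal"]
ref <- fit_reference(score_images(normals, model)$raw_as)
scores <- score_images(images, model, lambda = 0.95, ref = ref, ids = meta$id)
scores$label <- meta$label
write.csv(scores, "results/scores.csv", row.names = FALSE)
jsonlite::write_json(unclass(ref), "results/reference.json", auto_unbox = TRUE,
                     digits = NA)

cat("median standardized anomaly score by label:\n")
med <- aggregate(z_as ~ label, scores, median)
print(med, row.names = FALSE)
cat(sprintf("\n%d images scored; reference: mean %.5f, sd %.5f (n = %d)\n",
            nrow(scores), ref$mean, ref$sd, ref$n_reference))
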