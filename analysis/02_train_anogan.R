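#!/usr/bin/env Rscript
# Train the anomaly GAN (critic + generator, then the izi_f encoder) on the
# normal phantom renders simulated by 01_simulate_phantoms.R.
suppressPackageStartupMessages(library(anoscore))

meta <- read.csv("results/images/labels.csv")
normals <- lapply(file.path("results/images", meta$file[meta$label == "normal"]),
                  read_image_png)
cat(sprintf("training on %d normal renders\n", length(normals)))

hp <- gan_hyperparams(input_size = 48, latent_dim = 16, batch_size = 16,
                      hidden_units = c(96, 48), seed = 2026)
model <- train_wgan(normals, hp, n_steps = 600)
model <- train_encoder(model, normals, hp, n_steps = 400)
save_gan_model(model, "results/model")

tl <- model$training_log
el <- model$encoder_log
cat(sprintf("Wasserstein estimate: first 50 steps %.3f -> last 50 steps %.3f\n",
            mean(abs(head(tl$wasserstein, 50))),
            mean(abs(tail(tl$wasserstein, 50)))))
cat(sprintf("encoder loss_izi: first 10%% median %.4f -> last 10%% median %.4f\n",
            median(head(el$loss_izi, 40)), median(tail(el$loss_izi, 40))))
cat("checkpoint written to results/model\n")
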