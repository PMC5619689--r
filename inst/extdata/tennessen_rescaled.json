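{
  "schema": "reclethal-demography/1",
  "name": "Tennessen (sizes x1.96, times x1.967)",
  "burnin_Ne": 14328,
  "burnin_generations": 143280,
  "split_gen": 4012,
  "epochs": {
    "population": ["AFR", "AFR", "EUR", "EUR", "EUR"],
    "start": [11643, 401, 4012, 1809, 401],
    "end": [401, 0, 1809, 401, 0],
    "size_model": ["constant", "exponential", "constant", "exponential", "exponential"],
    "N_start": [28370, 28370, 3648, 2023, 18229],
    "N_end": [28370, 831063, 3648, 18229, 1003548]
  },
  "migration": {
    "start": [4012, 1809],
    "end": [1809, 0],
    "m_AFR_EUR": [7.6271186440678e-05, 1.27118644067797e-05],
    "m_EUR_AFR": [7.6271186440678e-05, 1.27118644067797e-05]
  }
}
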