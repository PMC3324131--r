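>patient01 synthetic
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYMCDEFGHIKLMNPQRSTVWYACDEFGDITKMNPVRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDVFGHIKLMNPQRSTVWYACDEFGHIKLMNPQYSTVKYACDEFGHIKLMNPQRSTVWY
>patient02 synthetic
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYMCDEFGHIKLMNPQRSTVWYACDEFGDITKMNPLRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDVFGHIKLMNPQRSTVWYACDEFGHIKLMNPQTSTVKYACDEFGHIKLMNPQRSTVWY
>patient03 synthetic
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYLCDEFGHIKLMNPQRSTVWYACDEFGDITKMNPLRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDVFGHIKLMNPQRSTVWYACDEFGHIKLMNPQTSTVKYACDEFGHIKLMNPQRSTVWY
>patient04 synthetic
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYMCDEFGHIKLMNPQRSTVWYACDEFGDITKMNPLRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDVFGHIKLMNPQRSTVWYACDEFGHIKWMNPQYSTVKYACDEFGHIKLMNPQRSTVWY
>patient05 synthetic
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYLCDEFGHIKLMNPQRSTVWYACDEFGDITRMNPLRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDVFGHIKLMNPQRSTVWYACDEFGHIKLMNPQYSTVKYACDEFGHIKLMNPQRSTVWY
>patient06 synthetic
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYLCDEFGHIKLMNPQRSTVWYACDEFGDIDKMNPLRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDVFGHIKLMNPQRSTVWYACDEFGHIKWMNPQTSTVKYACDEFGHIKLMNPQRSTVWY
>patient07 synthetic
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYLCDEFGHIKLMNPQRSTVWYACDEFGDITKMNPLRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDVFGHIKLMNPQRSTVWYACDEFGHIKLMNPQTSTVQYACDEFGHIKLMNPQRSTVWY
>patient08 synthetic
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYMCDEFGHIKLMNPQRSTVWYACDEFGDITKMNPLRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDVFGHIKLMNPQRSTVWYACDEFGHIKWMNPQTSTVKYACDEFGHIKLMNPQRSTVWY
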