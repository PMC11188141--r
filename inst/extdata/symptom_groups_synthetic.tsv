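group	term
facial_dysmorphism	HP:SYN0001
facial_dysmorphism	HP:SYN0002
facial_dysmorphism	HP:SYN0003
facial_dysmorphism	HP:SYN0004
facial_dysmorphism	HP:SYN0005
facial_dysmorphism	HP:SYN0006
facial_dysmorphism	HP:SYN0007
facial_dysmorphism	HP:SYN0008
facial_dysmorphism	HP:SYN0009
facial_dysmorphism	HP:SYN0010
facial_dysmorphism	HP:SYN0011
facial_dysmorphism	HP:SYN0012
facial_dysmorphism	HP:SYN0013
facial_dysmorphism	HP:SYN0014
facial_dysmorphism	HP:SYN0015
facial_dysmorphism	HP:SYN0016
facial_dysmorphism	HP:SYN0017
facial_dysmorphism	HP:SYN0018
neurodevelopmental	HP:SYN0019
neurodevelopmental	HP:SYN0020
neurodevelopmental	HP:SYN0021
neurodevelopmental	HP:SYN0022
neurodevelopmental	HP:SYN0023
neurodevelopmental	HP:SYN0024
neurodevelopmental	HP:SYN0025
neurodevelopmental	HP:SYN0026
neurodevelopmental	HP:SYN0027
neurodevelopmental	HP:SYN0028
neurodevelopmental	HP:SYN0029
neurodevelopmental	HP:SYN0030
neurodevelopmental	HP:SYN0031
neurodevelopmental	HP:SYN0032
neurodevelopmental	HP:SYN0033
growth	HP:SYN0034
growth	HP:SYN0035
growth	HP:SYN0036
growth	HP:SYN0037
growth	HP:SYN0038
growth	HP:SYN0039
growth	HP:SYN0040
growth	HP:SYN0041
growth	HP:SYN0042
growth	HP:SYN0043
skeletal	HP:SYN0044
skeletal	HP:SYN0045
skeletal	HP:SYN0046
skeletal	HP:SYN0047
skeletal	HP:SYN0048
skeletal	HP:SYN0049
skeletal	HP:SYN0050
skeletal	HP:SYN0051
skeletal	HP:SYN0052
skeletal	HP:SYN0053
skeletal	HP:SYN0054
skeletal	HP:SYN0055
cardiovascular	HP:SYN0056
cardiovascular	HP:SYN0057
cardiovascular	HP:SYN0058
cardiovascular	HP:SYN0059
cardiovascular	HP:SYN0060
cardiovascular	HP:SYN0061
cardiovascular	HP:SYN0062
cardiovascular	HP:SYN0063
cardiovascular	HP:SYN0064
cardiovascular	HP:SYN0065
ophthalmological	HP:SYN0066
ophthalmological	HP:SYN0067
ophthalmological	HP:SYN0068
ophthalmological	HP:SYN0069
ophthalmological	HP:SYN0070
ophthalmological	HP:SYN0071
ophthalmological	HP:SYN0072
ophthalmological	HP:SYN0073
ophthalmological	HP:SYN0074
ophthalmological	HP:SYN0075
audiological	HP:SYN0076
audiological	HP:SYN0077
audiological	HP:SYN0078
audiological	HP:SYN0079
audiological	HP:SYN0080
audiological	HP:SYN0081
audiological	HP:SYN0082
audiological	HP:SYN0083
dermatological	HP:SYN0084
dermatological	HP:SYN0085
dermatological	HP:SYN0086
dermatological	HP:SYN0087
dermatological	HP:SYN0088
dermatological	HP:SYN0089
dermatological	HP:SYN0090
dermatological	HP:SYN0091
dermatological	HP:SYN0092
dermatological	HP:SYN0093
urogenital	HP:SYN0094
urogenital	HP:SYN0095
urogenital	HP:SYN0096
urogenital	HP:SYN0097
urogenital	HP:SYN0098
urogenital	HP:SYN0099
urogenital	HP:SYN0100
urogenital	HP:SYN0101
gastrointestinal	HP:SYN0102
gastrointestinal	HP:SYN0103
gastrointestinal	HP:SYN0104
gastrointestinal	HP:SYN0105
gastrointestinal	HP:SYN0106
gastrointestinal	HP:SYN0107
gastrointestinal	HP:SYN0108
gastrointestinal	HP:SYN0109
immunological	HP:SYN0110
immunological	HP:SYN0111
immunological	HP:SYN0112
immunological	HP:SYN0113
immunological	HP:SYN0114
immunological	HP:SYN0115
Others	HP:SYN0116
Others	HP:SYN0117
Others	HP:SYN0118
Others	HP:SYN0119
Others	HP:SYN0120
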