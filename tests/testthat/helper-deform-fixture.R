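# Frozen oracle fixture for the depthwise deformable 3x3 convolution:
# input, kernel, bias, offset field and expected output of a reference
# deformable-convolution implementation (double precision).
fix_x <- array(c(0.29955628775026372, 0.39000348360357029, 0.78176737425469756, 0.86517346471190737, 0.42851736454334621, -0.18737793842779638, -1.4920727283504345, -0.44197455027756111, -0.037203007270524932, -1.3457475275202437, 0.24237779080894106, -0.57984145547421084, -1.7903080050220619, 0.85521596147228696, 0.2318702888580676, 0.44282680847527639, 0.42120099470667788, -0.90174211480828148, 1.0352472972512925, 1.1755166198951001, 0.28320739441795323, 0.87589388464802198, -1.748402801489203, 0.65511430527310477, -1.0214571469180447, -0.23210767943346114, 1.504572275678796, -1.1149258145774585, -0.010085521702337353, -2.6327923840518515, -0.23294220898382634, 0.39238484373268534, 0.17347640142361004, 0.62848355239981446, -0.82726322923810214, -0.03265155768725795, 1.2715909667771088, 1.1145903864961688, 0.089480160465603573, 0.57814758064101524, 0.67115322119230025, 1.1084611814514329, 0.26684314514213736, -1.108152357089335, 1.7342104609172728, -2.4472388194699217, 0.61866999388561705, 0.03089355171661811, 0.084030177658937166, 0.34666368467190317), dim = c(1, 2, 5, 5))
fix_w <- array(c(-0.42612487485896516, 0.78055736787127572, -1.3609061518632273, -0.13251885607663033, -0.071874966335519166, -0.13669766485942028, 1.0706958079661568, 0.55246714594184598, 0.33965196927586733, 0.76586986155901504, -0.17850995418741708, 0.41237563854231823, 0.89813479485055026, 0.036700015262864455, -0.21409556674925639, -0.026812967640530101, 1.0735486699835646, -0.19183479733456638), dim = c(2, 1, 3, 3))
fix_b <- c(0.1, -0.2)
fix_off <- array(c(-0.58935404806774538, -0.30678501619634441, -0.15277988468291698, 1.2735508492323178, -0.96247170006958394, -1.1968194516762878, -0.17589571532505555, 0.65626055883282786, -0.88427128695005341, -0.10038459878340537, 0.51727824475918815, 0.50395722580629754, 1.4008266370901075, 0.60739133820349511, -0.47581615979372599, 0.065031436304668067, 0.48759444447031225, -0.076261725906472663, 0.86896498600900973, -0.43395119892940287, -0.11741680473806979, -0.13277404737533938, -0.48921825210933079, 1.082647573916671, 0.96726945973084222, 0.58646915630476382, -0.010551322541754738, 0.13908529254189941, -1.0885058275948993, 0.0071437295904586045, -0.14399313462830934, -1.0143564766677795, -0.1007216560583141, 0.036858973990949701, -0.062784042793703684, -0.62184757442161942, 0.66749952702968551, 0.49711161777922108, 1.1360283646311278, -0.84715429370750039, -0.11630224089112577, 0.79572428687751029, 0.065903729896390137, -0.23131435053827601, -0.08554302413719686, 0.65978396897301295, 1.8575856888785691, -0.18617833898886321, -0.71870844886191587, -0.068079472575999417, -1.1906505889883383, -0.12637461940206474, 1.5273101796070165, -0.43440190438681031, -0.67141437566425399, 0.44043582965564537, 0.70937331899397615, -1.0714762945055669, 1.2699135783709468, 0.29912010875582878, -0.12657766291108402, 0.10161452619745785, -0.22065300264935772, 0.35410975156682267, -1.0372042235215633, 0.18840861588619379, 0.23143621508518866, -1.0192531381452659, -1.2843169022628071, -0.41575574910320123, -0.0024211258838606245, 0.78064126307538539, 0.075338077511072063, -0.33739552361666508, -0.90016645209848811, 0.20620874137261733, -0.47287320364960395, 0.43429615762252055, -0.6427216003338978, -0.85666280148213858, -1.4331204407881126, -0.20137246555231286, 0.51326128237965907, -0.3924587735795666, -0.18611070534143198, -0.092806588143019786, 1.0008387130216867, -0.62238951755232508, -1.1734675824058354, 1.0203312030182667, -0.37774695910738204, 1.7134533878079039, -0.74157658256420267, 0.20962833831434136, -0.31180107425688525, -0.75436169044946055, 1.0505800440177517, -0.63203044760951632, 1.0168234309738482, 0.13931797898932757, 0.46512041029616447, -0.53250486708504219, 0.1351389636707809, -0.0024789973650953109, -0.17885317708535461, 1.1952853425063406, -0.23520503637269297, -0.51882093614925873, 0.19017926340227478, -0.48362971411926753, -0.15517053697729771, -0.27198456227675921, -1.0780689407245516, -0.12107852165065305, 0.81630199010446913, 0.47916907135290099, 0.7078522194919018, -0.1740345351379633, 0.42699553080125846, -0.61868918606481671, 0.29509174144168993, -0.40813865427197538, -0.52467925816200223, -0.15442424624386944, -0.71724848560409205, 0.48484509739029485, 0.80633265613100435, -0.48624646583637476, -0.16567947844878989, -0.52010447975521312, 0.0044473737795986392, 0.21039360391824372, -0.16125147183110627, -0.2732255172290638, -1.0546627220064206, -0.067078228485875468, 0.72974218311190397, -0.11004171016813601, 0.73527802581266233, -0.10267786236065277, -0.24105645784037405, -0.15542714139862254, -0.38481698667823416, 0.57401941610664875, 0.59093078091966322, -0.60636903459274616, -0.68760082290465185, 0.016581400762402967, 0.48396784536561394, -0.83364246009783105, 0.10536394180169684, 0.054385797949016108, -0.19407385342730901, 0.072692206888993374, -0.10726473532606455, -0.06719607477940602, 0.013556627310408659, 0.99593043174581775, 0.45985198365205143, 0.010702274212756744, 1.9033018165368567, 0.98480179995043515, 0.46004740894179869, 0.71742573423355382, -1.1661259364757797, 1.1521754003210092, -0.36193675180826496, 1.1422483688266063, 0.56473548804355467, 1.6546297971934119, 0.039285253587486454, -1.0322443412391966, 0.6677342167176622, 0.099266233996225722, 0.0077727280750696931, 0.60355028536932065, -0.20282135186717914, 0.66849893579858899, 0.24376832466535511, 0.67161160401656861, -1.0662326105844857, -0.90072214331500222, 0.2177461414920171, 0.084217075436674033, 0.043364649794389525, 0.18825779068466664, 0.73534572639224804, -0.2803924732769108, 0.48504761091963261, -1.0780401523084528, 0.010890481611139294, -1.0125507562635783, -1.8159148041167805, -0.11547405424532851, -0.43921519421397709, 1.0170260420113755, -0.23516206236157969, -0.088836528340433554, 0.0054182619064019064, 0.67450564097850829, -0.99449950148493904, -0.55052016614592891, -0.35967807417968073, 0.76691840367783781, 0.34817876274128878, -0.44821921667991843, 0.63194391754938117, 0.12501946716666293, -0.077099883181677806, 0.56480040187180358, -0.39952784342863507, 0.92351316656361104, -0.12177733990212387, -0.66700385380302651, 0.89235020832888801, 0.27185700719845463, 0.14069144296168123, -1.1758732981018918, 0.18739323198902114, 0.095143024328433315, 0.12524175838844159, -0.8688133416387307, -1.32987383719539, 1.0490902838371166, 0.63327194066666548, 0.35455630756086376, -0.64776029977051031, 0.31372240641555582, -0.64849529602242351, 0.41626606661852594, -0.66868664870232508, -0.36612179238717307, 0.61982436626268089, 0.7354724740335814, -0.065011231104668207, 0.2132146578817701, 1.6975038474428377, 0.18963143503672361, -0.46702079518717815, -1.0774239398043881, 0.84195663616026828, 0.594214801748148, -0.57194064149317603, -0.98536811206405295, 0.76322140186875587, 0.47782503872401288, 1.0688460290035569, -0.68254947038189928, -0.40293795943208244, 0.48668764866962394, 0.084973685768204507, -0.077326461021577766, 0.34869621029468623, 0.040285222839785091, -1.5401695929150285, 0.29163929905371261, -0.7217188977811666, -0.52380391668431203, -1.3827547625583558, -0.036275239293976032, 0.15102860904275836, -0.55739569462689742, 0.72965899156857539, -0.33858799899509961, 0.70777151166467422, -0.46567511374954296, 0.6967624503690113, 0.51746269082184304, 0.29868594907774465, -0.61249211136618698, 0.37207284758260628, 0.99429346881895753, 0.68697737836453232, 0.47290751194674718, 0.51730246655314371, 1.5265123600550574, 0.16029524199532222, -0.94598588582399024, 0.24046125069398047, 0.6356877263309183, -0.50581172566798138, -0.13858514716078538, -0.23174009473102136, -0.35932656291255044, -0.42143760317397366, 1.0875015544173616, -0.94176560021710598, 0.32480627644572135, -0.31742669728653256, -0.43970715333227933, -0.33387892789489765, -1.2384806130202561, 1.0761698554005668, -0.64049573766686407, 0.01631639105287146, -0.79279551886686084, -0.85215502565338042, -0.4738229504860384, -0.93055700246520434, 0.20947516338286401, -0.49616116214566364, 0.43688905957877461, 0.38847741171693612, 0.93491914196582371, 1.2366135063357875, -0.8038388656047295, 0.16881417786460134, -0.84266560622316522, 1.1253746269936342, -0.81811212179479076, 0.47278075438196326, -0.53233343490655027, 0.66350073841015766, -0.97087069719722574, -0.82797135780056308, 0.11215758636832779, -0.30553753525410082, 0.532836495356937, 0.10352055406405546, -0.33270097441881197, -1.4865868827110518, -0.35514266389936411, -0.1885647369761165, -0.16694237156570846, -0.48899561248109008, 1.4910892714364894, 0.80630812502256766, -0.55111333047916755, -0.11654602188109997, 0.47064418221218957, 0.86351006354269122, 0.23206505274996378, 0.07729278835468438, 0.72097256573999779, -0.23176014919029822, -0.27963480578719524, 1.5836031274532731, -0.21100765843143446, 1.0489537289431545, 0.90265022177408949, -1.5852436739373368, 0.34152086303005053, 0.49461715362019504, -0.72402314317932082, -0.82163213706860427, 0.45626136454990363, 0.71868687158844691, 0.025759561261978137, 0.28434864340220573, -0.78399028776415924, 0.61749653817833072, 1.2677301892615049, 1.0881548700070258, -0.87002864899616672, -0.81661248282411592, -0.55719986816216194, 0.19479355320884459, -0.1663223044991935, -0.90602823402907506, 0.016256406228449018, 1.0712627161658244, 0.03031118608935069, -0.94500998319479623, -1.4627748760260146, -0.2445393347962285, 0.27680568621453122, 1.0883421779006528, -0.63125956117560555, 0.37049287865412123, 0.54871361336765878, -0.16210678829153238, -0.4107199311781779, 0.43151291332210767, -0.38135439971641794, 0.91918557189717642, 0.57019991551805538, 0.086498567348084129, -0.076809611440098222, -0.55479682592214774, -0.18780744370353736, 0.63672284897296194, 0.51481594509591322, 0.52798692850798234, -0.86576488869933566, 0.11576544621257484, 1.3944318390871233, 0.86200538879460664, 0.5952981088227427, 0.49712509349434242, 0.26925047794299622, 1.3780878641466172, 0.5364369086588433, 0.49345907763016766, 0.93099165641460113, 1.5773011555778531, -0.57999116321571331, 0.75854492222516257, -0.47856496384890912, 0.16095594184222267, 0.64538843996518058, 0.49661745770769916, -0.69800370099316444, 0.12291884585541801, 0.080581491184917739, 0.25826680017322973, 0.19900683928794211, 0.40057697274338483, -0.61804326819797384, 0.0048507458808824616, 0.82870722123514384, -0.097995701935524884, 0.16618035147378998, -0.57714191348498234, 0.14693917858128139, 0.14982715780032435, 0.64067265726000244, 0.38825004113308692, 0.90506564442138515, 0.44157963746052992, 0.70893733303574957, 0.97423450599076922, 0.090238567384623228, 0.016883649732790398, 0.3808897723350006, 0.24701584486338635, 0.078379392217484856, -0.85518538906180752, -0.088838735755921272, -0.28555609785802766, -0.22667483468394922, 0.21517022106974815, -0.1653858119458807, -1.4598671323204095, 0.30233670804638518, 1.6199078170366927, 0.26692079756927567, 0.54518444813360378, -1.766168881253642, 0.80336257089075103, -1.0665665454316913, -0.8933604639878312, -1.040073403572034, 1.1094811481271338, 0.19110037471169544, 1.1080024281558436, 0.059360951744626016, 0.91926890827796637, -0.17697780748542646, -1.4348069326977229, 1.3810973839319542), dim = c(1, 18, 5, 5))
fix_y <- array(c(-0.75656601428254644, -0.055316727055184173, 0.46428155575365015, 0.6185334456516749, -1.2316283499234069, 0.070001792258552298, 0.97470146047635842, -0.14993430130275653, 0.67511539241542218, -0.037422621229832698, -1.9761133029224656, 0.43927648188799867, -0.63671618512733141, 0.36432963465838303, -2.2022687765109557, 0.74168085098189795, 0.65289064605274838, -0.22894268395632295, -0.86741206669015591, -1.3509589786122356, 0.80704728246166424, 0.036068371584976611, 1.4089089905302417, 0.11704570302954098, -1.0814908028985823, 0.084233844541860003, -1.2194034559711433, -1.1320233614939881, -1.8506175866244896, -0.51663631067972493, 0.93070461652416681, 0.3423002971766918, 3.4482364652234132, -0.2821359376183088, 0.60407690927657531, 0.82717757183877638, 2.4036506213635547, -0.21212719827924209, -0.25458333314820514, -0.93678510489762701, 1.5699469363595842, -0.29458861117843538, 0.68216362423115484, -0.84248347900707254, 1.888934641730277, -1.6372043019661886, -0.26787726286546487, -1.306637781069232, 0.97380388414577257, 0.39398767944067786), dim = c(1, 2, 5, 5))
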